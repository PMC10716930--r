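# Monte Carlo tree search over SMILES token space.
#
# The tree is grown over token prefixes; the language model supplies the
# prior over child tokens and the rollout policy; a plug-in reward in
# [0, 1] is evaluated on molecules that parse and pass the generation
# filters and is backpropagated along the selection path. Filtered or
# invalid proposals backpropagate zero by default.

#' Construct a reward function
#'
#' @param name Short name recorded in generation logs.
#' @param evaluate Function taking one evaluated-molecule record (a list
#'   with at least `inchikey_nostereo` and `canonical_smiles`) and
#'   returning a reward in `[0, 1]`.
#' @return A `reward_function`.
#' @export
reward_function <- function(name, evaluate) {
  stopifnot(is.character(name), is.function(evaluate))
  structure(list(name = name, evaluate = evaluate),
            class = "reward_function")
}

#' @export
print.reward_function <- function(x, ...) {
  cat("<reward_function>", x$name, "\n")
  invisible(x)
}

#' Patent-membership reward functions
#'
#' `r_patent(db)` scores 1 exactly when the molecule's stereo-free
#' InChIKey is present in the drug-patent database, else 0;
#' `r_not_patent(db)` is its complement, steering the search away from
#' patented structures. `r_rand(seed)` ignores the molecule and returns
#' uniform draws on `[0, 1)` from its own seeded stream (baseline).
#'
#' @param db A `drug_patent_db`.
#' @return A [reward_function()].
#' @export
r_patent <- function(db) {
  holder <- new.env(parent = emptyenv())
  holder$con <- db_connect(db)
  reg.finalizer(holder, function(e) {
    try(DBI::dbDisconnect(e$con), silent = TRUE)
  }, onexit = TRUE)
  sql <- sprintf("SELECT 1 FROM %s WHERE inchikey = ? LIMIT 1",
                 db_table(holder$con))
  reward_function("patent", function(mol) {
    hit <- DBI::dbGetQuery(holder$con, sql,
                           params = list(mol$inchikey_nostereo))
    as.numeric(nrow(hit) > 0)
  })
}

#' @rdname r_patent
#' @export
r_not_patent <- function(db) {
  base <- r_patent(db)
  reward_function("not-patent", function(mol) 1 - base$evaluate(mol))
}

#' @rdname r_patent
#' @param seed Seed of the private random stream.
#' @export
r_rand <- function(seed = 1L) {
  # private linear congruential stream so reward draws never perturb (or
  # depend on) the session RNG used by the sampler
  state <- as.double(seed %% 2147483647)
  reward_function("random", function(mol) {
    state <<- (state * 1103515245 + 12345) %% 2147483648
    state / 2147483648
  })
}

#' Generation filter switches
#'
#' @param rare_pattern,lipinski,radical,sa,ring Enable the corresponding
#'   filter.
#' @return Named logical vector.
#' @export
filter_switches <- function(rare_pattern = TRUE, lipinski = TRUE,
                            radical = TRUE, sa = TRUE, ring = TRUE) {
  c(rare_pattern = rare_pattern, lipinski = lipinski, radical = radical,
    sa = sa, ring = ring)
}

#' Apply the five generation filters
#'
#' Verdicts (`TRUE` = pass) for: `rare_pattern` (configurable
#' substructure list; fails on any hit), `lipinski` (fails iff molecular
#' weight > 500, SlogP > 5, H-bond donors > 5 or acceptors > 10),
#' `radical` (fails iff any radical electrons), `sa` (fails iff synthetic
#' accessibility score >= 3.5), `ring` (fails iff largest ring > 6
#' atoms). `pass` is the conjunction over enabled filters; disabled
#' filters are reported `NA` and ignored.
#'
#' @param descriptors A data frame with columns `mol_weight`, `slogp`,
#'   `hbd`, `hba`, `n_radical_electrons`, `sa_score`, `max_ring_size` and
#'   (for the rare-pattern filter) `blacklist_hit`; one row per molecule.
#' @param switches From [filter_switches()].
#' @return A tibble of per-filter verdicts plus `pass`.
#' @export
apply_filters <- function(descriptors, switches = filter_switches()) {
  d <- tibble::as_tibble(descriptors)
  v <- tibble::tibble(
    rare_pattern = if (switches[["rare_pattern"]]) {
      !(d$blacklist_hit %||% rep(FALSE, nrow(d)))
    } else {
      NA
    },
    lipinski = if (switches[["lipinski"]]) {
      !(d$mol_weight > 500 | d$slogp > 5 | d$hbd > 5 | d$hba > 10)
    } else {
      NA
    },
    radical = if (switches[["radical"]]) d$n_radical_electrons == 0 else NA,
    sa = if (switches[["sa"]]) d$sa_score < 3.5 else NA,
    ring = if (switches[["ring"]]) d$max_ring_size <= 6 else NA
  )
  enabled <- names(switches)[switches]
  v$pass <- if (length(enabled) == 0) {
    rep(TRUE, nrow(v))
  } else {
    apply(v[, enabled, drop = FALSE], 1, all)
  }
  v
}

#' Generation configuration
#'
#' @param c_explore UCT exploration constant; larger values search wider.
#' @param switches Filter switches from [filter_switches()].
#' @param target_valid_unique Stop once this many valid unique molecules
#'   are logged (the evaluation-protocol budget).
#' @param max_iterations Hard iteration cap.
#' @param max_seconds Wall-clock cap.
#' @param seed Seed for all search randomness.
#' @param replicate_id Identifier recorded in the log.
#' @param prune_threshold Minimum language-model prior for a token to be
#'   expandable at a node.
#' @param temperature Rollout sampling temperature.
#' @param filtered_reward_mode `"zero"` backpropagates reward 0 for
#'   invalid/filtered proposals; `"skip"` leaves visit counts untouched.
#' @param blacklist SMARTS patterns for the rare-pattern filter.
#' @return A `generation_config` list.
#' @export
generation_config <- function(c_explore = 1.0,
                              switches = filter_switches(),
                              target_valid_unique = NULL,
                              max_iterations = NULL,
                              max_seconds = NULL,
                              seed = 1L, replicate_id = 1L,
                              prune_threshold = 1e-4,
                              temperature = 1.0,
                              filtered_reward_mode = c("zero", "skip"),
                              blacklist = default_substructure_blacklist()) {
  stopifnot(c_explore >= 0)
  if (is.null(target_valid_unique) && is.null(max_iterations) &&
      is.null(max_seconds)) {
    rlang::abort("set at least one budget", class = "patgen_config_error")
  }
  structure(
    list(c_explore = c_explore, switches = switches,
         target_valid_unique = target_valid_unique,
         max_iterations = max_iterations, max_seconds = max_seconds,
         seed = as.integer(seed), replicate_id = as.integer(replicate_id),
         prune_threshold = prune_threshold, temperature = temperature,
         filtered_reward_mode = match.arg(filtered_reward_mode),
         blacklist = blacklist),
    class = "generation_config"
  )
}

#' UCT child selection
#'
#' Among visited children returns the (1-based) index maximizing
#' `W_i / N_i + c * sqrt(2 * ln(N) / N_i)`; unvisited children
#' (`N_i = 0`) take priority, and ties break toward the lowest index.
#'
#' @param visit_counts,total_rewards Per-child `N_i` and `W_i`.
#' @param parent_visits Visit count `N` of the parent node.
#' @param c_explore Exploration constant.
#' @return Index of the selected child.
#' @export
uct_select <- function(visit_counts, total_rewards, parent_visits,
                       c_explore) {
  if (length(visit_counts) == 0) {
    rlang::abort("no child to select", class = "patgen_no_expandable_child")
  }
  if (any(visit_counts == 0)) return(which(visit_counts == 0)[1])
  score <- total_rewards / visit_counts +
    c_explore * sqrt(2 * log(max(parent_visits, 1)) / visit_counts)
  which.max(score)
}

#' Chemistry evaluator for proposed SMILES
#'
#' Returns a memoized function mapping a proposed SMILES string to its
#' evaluation record: parse validity, standardized structure and key,
#' filter descriptors and blacklist hit (one worker round-trip per new
#' string).
#'
#' @param blacklist SMARTS patterns for the rare-pattern filter.
#' @return Function `(smiles) -> list`.
#' @export
chem_evaluator <- function(blacklist = default_substructure_blacklist()) {
  cache <- new.env(parent = emptyenv())
  patterns <- as.list(unname(blacklist))
  function(smiles) {
    hit <- cache[[smiles]]
    if (!is.null(hit)) return(hit)
    rec <- chem_request("eval_generated",
                        list(smiles = list(smiles), patterns = patterns))[[1]]
    cache[[smiles]] <- rec
    rec
  }
}

new_search_node <- function(prefix_ids, terminal, untried) {
  e <- new.env(parent = emptyenv())
  e$prefix <- prefix_ids
  e$terminal <- terminal
  e$untried <- untried
  e$children <- list()
  e$child_tokens <- integer()
  e$N <- 0
  e$W <- 0
  # a terminal node is evaluated once and then exhausted; an internal node
  # is exhausted when nothing is left to expand and every child is
  # exhausted -- exhausted subtrees are excluded from selection so the
  # search enumerates rather than cycling on already-proposed strings
  e$exhausted <- FALSE
  e
}

#' Generate molecules by Monte Carlo tree search
#'
#' Each iteration selects a path from the root by [uct_select()], expands
#' one child token whose language-model prior exceeds the pruning
#' threshold (highest-prior untried token first), completes the prefix by
#' rollout sampling, evaluates the proposal (parse, standardize, filter),
#' computes the reward for surviving molecules, and backpropagates along
#' the path. Every proposed SMILES is appended to the log; the run stops
#' at the configured budget.
#'
#' @param lm A fitted language model ([train_lm()]) or any object with
#'   `next_token_distribution` and `sample_completion` methods and a
#'   `vocab` element.
#' @param reward A [reward_function()].
#' @param config A [generation_config()].
#' @param evaluator Proposal evaluator; defaults to
#'   [chem_evaluator()] with the config's blacklist. Tests may inject a
#'   synthetic evaluator for non-chemical token languages.
#' @return A `generation_log`: list with `config`, `records` (tibble, one
#'   row per proposal) and `totals` (`n_all`, `n_valid`,
#'   `n_valid_unique`).
#' @export
mcts_generate <- function(lm, reward, config,
                          evaluator = chem_evaluator(config$blacklist)) {
  stopifnot(inherits(reward, "reward_function"))
  vocab <- lm$vocab
  if (inherits(lm, "patent_lm")) lm <- lm_with_handle(lm)
  set.seed(config$seed)
  end_tok <- vocab$end_symbol
  banned <- c(vocab$pad_symbol, vocab$start_symbol)
  tok_names <- vocab$tokens

  allowed_tokens <- function(prefix_toks) {
    p <- next_token_distribution(lm, prefix_toks)
    ok <- which(p >= config$prune_threshold & !(tok_names %in% banned))
    ok[order(p[ok], decreasing = TRUE)]
  }

  make_node <- function(prefix_idx) {
    prefix_toks <- tok_names[prefix_idx]
    terminal <- (length(prefix_idx) > 0 &&
                   prefix_toks[length(prefix_toks)] == end_tok) ||
      length(prefix_idx) + 2L >= vocab$max_len
    untried <- if (terminal) integer() else allowed_tokens(prefix_toks)
    new_search_node(prefix_idx, terminal, untried)
  }

  # scalar fast path of apply_filters() for the inner loop
  sw <- config$switches
  filter_one <- function(rec) {
    c(rare_pattern = if (sw[["rare_pattern"]]) !isTRUE(rec$blacklist_hit) else NA,
      lipinski = if (sw[["lipinski"]]) {
        !(rec$mol_weight > 500 || rec$slogp > 5 || rec$hbd > 5 || rec$hba > 10)
      } else NA,
      radical = if (sw[["radical"]]) rec$n_radical_electrons == 0 else NA,
      sa = if (sw[["sa"]]) rec$sa_score < 3.5 else NA,
      ring = if (sw[["ring"]]) rec$max_ring_size <= 6 else NA)
  }

  root <- make_node(integer())
  cap <- 4096L
  col_iter <- integer(cap)
  col_smiles <- character(cap)
  col_valid <- logical(cap)
  col_canon <- character(cap)
  col_key <- character(cap)
  col_verd <- matrix(NA, nrow = cap, ncol = 5,
                     dimnames = list(NULL, c("rare_pattern", "lipinski",
                                             "radical", "sa", "ring")))
  col_pass <- logical(cap)
  col_reward <- rep(NA_real_, cap)
  col_new <- logical(cap)
  n_rec <- 0L
  unique_keys <- new.env(parent = emptyenv())
  n_valid <- 0L
  n_valid_unique <- 0L
  iteration <- 0L
  t0 <- proc.time()[["elapsed"]]

  over_budget <- function() {
    (!is.null(config$target_valid_unique) &&
       n_valid_unique >= config$target_valid_unique) ||
      (!is.null(config$max_iterations) &&
         iteration >= config$max_iterations) ||
      (!is.null(config$max_seconds) &&
         proc.time()[["elapsed"]] - t0 >= config$max_seconds)
  }

  while (!over_budget() && !root$exhausted) {
    iteration <- iteration + 1L
    node <- root
    path <- list(root)
    # selection (over non-exhausted children only)
    while (!node$terminal && length(node$untried) == 0 &&
             length(node$children) > 0) {
      live <- which(!vapply(node$children, function(ch) ch$exhausted,
                            logical(1)))
      Ns <- vapply(node$children[live], function(ch) ch$N, numeric(1))
      Ws <- vapply(node$children[live], function(ch) ch$W, numeric(1))
      pick <- live[uct_select(Ns, Ws, node$N, config$c_explore)]
      node <- node$children[[pick]]
      path[[length(path) + 1L]] <- node
    }
    # expansion
    if (!node$terminal && length(node$untried) > 0) {
      tok <- node$untried[1]
      node$untried <- node$untried[-1]
      child <- make_node(c(node$prefix, tok))
      node$children[[length(node$children) + 1L]] <- child
      node$child_tokens <- c(node$child_tokens, tok)
      node <- child
      path[[length(path) + 1L]] <- node
    }
    # rollout
    prefix_toks <- tok_names[node$prefix]
    smiles <- if (node$terminal) {
      detokenize_smiles(prefix_toks[prefix_toks != end_tok])
    } else {
      sample_completion(lm, prefix_toks, temperature = config$temperature)
    }
    rec <- if (nzchar(smiles)) evaluator(smiles) else list(parse_valid = FALSE)
    parse_valid <- isTRUE(rec$parse_valid)
    if (parse_valid) {
      verdicts <- filter_one(rec)
      passed <- all(verdicts[sw])
    } else {
      verdicts <- rep(NA, 5)
      passed <- FALSE
    }
    rew <- if (passed) reward$evaluate(rec) else NA_real_
    valid <- parse_valid && passed
    is_new <- FALSE
    if (valid) {
      n_valid <- n_valid + 1L
      key <- rec$canonical_smiles
      if (is.null(unique_keys[[key]])) {
        unique_keys[[key]] <- TRUE
        n_valid_unique <- n_valid_unique + 1L
        is_new <- TRUE
      }
    }
    # backpropagation
    if (passed || config$filtered_reward_mode == "zero") {
      bp <- if (passed) rew else 0
      for (nd in path) {
        nd$N <- nd$N + 1
        nd$W <- nd$W + bp
      }
    }
    # exhaustion propagation from the evaluated node toward the root
    if (node$terminal) node$exhausted <- TRUE
    for (di in rev(seq_along(path))) {
      nd <- path[[di]]
      if (!nd$terminal && length(nd$untried) == 0 &&
            length(nd$children) > 0 &&
            all(vapply(nd$children, function(ch) ch$exhausted, logical(1)))) {
        nd$exhausted <- TRUE
      }
    }
    n_rec <- n_rec + 1L
    if (n_rec > cap) {
      cap <- cap * 2L
      grow <- function(x) {
        length(x) <- cap
        x
      }
      col_iter <- grow(col_iter)
      col_smiles <- grow(col_smiles)
      col_valid <- grow(col_valid)
      col_canon <- grow(col_canon)
      col_key <- grow(col_key)
      col_pass <- grow(col_pass)
      col_reward <- grow(col_reward)
      col_new <- grow(col_new)
      v2 <- matrix(NA, nrow = cap, ncol = 5, dimnames = dimnames(col_verd))
      v2[seq_len(nrow(col_verd)), ] <- col_verd
      col_verd <- v2
    }
    col_iter[n_rec] <- iteration
    col_smiles[n_rec] <- smiles
    col_valid[n_rec] <- parse_valid
    col_canon[n_rec] <- if (parse_valid) rec$canonical_smiles else NA_character_
    col_key[n_rec] <- if (parse_valid) rec$inchikey_nostereo else NA_character_
    col_verd[n_rec, ] <- as.logical(verdicts)
    col_pass[n_rec] <- passed
    col_reward[n_rec] <- rew
    col_new[n_rec] <- is_new
  }

  ii <- seq_len(n_rec)
  records <- tibble::tibble(
    iteration = col_iter[ii],
    smiles = col_smiles[ii],
    parse_valid = col_valid[ii],
    canonical_smiles = col_canon[ii],
    inchikey_nostereo = col_key[ii],
    rare_pattern = col_verd[ii, "rare_pattern"],
    lipinski = col_verd[ii, "lipinski"],
    radical = col_verd[ii, "radical"],
    sa = col_verd[ii, "sa"],
    ring = col_verd[ii, "ring"],
    passed = col_pass[ii],
    reward = col_reward[ii],
    new_unique = col_new[ii]
  )
  structure(
    list(
      config = config,
      reward_name = reward$name,
      records = records,
      totals = list(n_all = n_rec, n_valid = n_valid,
                    n_valid_unique = n_valid_unique),
      elapsed_seconds = proc.time()[["elapsed"]] - t0
    ),
    class = "generation_log"
  )
}

#' @export
print.generation_log <- function(x, ...) {
  cat("<generation_log> reward ", x$reward_name, ", C ",
      x$config$c_explore, ": ", x$totals$n_all, " proposals, ",
      x$totals$n_valid, " valid, ", x$totals$n_valid_unique,
      " valid-unique\n", sep = "")
  invisible(x)
}

#' @rdname mcts_generate
#' @param x A `generation_log`.
#' @param ... Unused.
#' @export
tidy.generation_log <- function(x, ...) x$records

#' @rdname mcts_generate
#' @export
glance.generation_log <- function(x, ...) {
  tibble::tibble(
    reward = x$reward_name,
    c_explore = x$config$c_explore,
    seed = x$config$seed,
    replicate_id = x$config$replicate_id,
    n_all = x$totals$n_all,
    n_valid = x$totals$n_valid,
    n_valid_unique = x$totals$n_valid_unique,
    elapsed_seconds = x$elapsed_seconds
  )
}

#' Write / read generation logs
#'
#' The record stream is written as JSON-lines (one proposal per line) with
#' a `summary.json` sidecar holding the config and totals.
#'
#' @param log A `generation_log`.
#' @param path Output path for the `.jsonl` stream.
#' @return `write_generation_log`: `path` invisibly;
#'   `read_generation_log`: the restored `generation_log`.
#' @export
write_generation_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log$records))) {
    writeLines(jsonlite::toJSON(as.list(log$records[i, ]),
                                auto_unbox = TRUE, na = "null", digits = NA),
               con)
  }
  summary_path <- paste0(path, ".summary.json")
  jsonlite::write_json(
    list(config = unclass(log$config)[setdiff(names(log$config), "switches")],
         switches = as.list(log$config$switches),
         reward = log$reward_name, totals = log$totals,
         elapsed_seconds = log$elapsed_seconds),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_generation_log
#' @export
read_generation_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- dplyr::bind_rows(lapply(lines, function(l) {
    obj <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    obj <- lapply(obj, function(x) if (is.null(x)) NA else x)
    tibble::as_tibble(obj)
  }))
  smry <- jsonlite::fromJSON(paste0(path, ".summary.json"),
                             simplifyVector = TRUE)
  structure(
    list(config = smry$config, reward_name = smry$reward,
         records = records, totals = as.list(smry$totals),
         elapsed_seconds = smry$elapsed_seconds),
    class = "generation_log"
  )
}
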