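// Gated-recurrent-unit SMILES language model: embedding -> stacked GRU
// layers -> softmax head, trained by truncated-free full BPTT with Adam.
// All randomness (init, shuffling, dropout, sampling) draws from R's RNG
// so set.seed() in R controls every stochastic path.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::IntegerVector;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::stop;

struct GruModel {
  int V, D, H, L;
  mat Emb;                 // D x V
  std::vector<mat> W;      // 3H x Din  (gate rows: [z; r; n])
  std::vector<mat> U;      // 3H x H
  std::vector<vec> b;      // 3H
  mat Why;                 // V x H
  vec by;                  // V
};

static GruModel from_list(const List &p) {
  GruModel m;
  m.Emb = Rcpp::as<mat>(p["Emb"]);
  m.D = m.Emb.n_rows;
  m.V = m.Emb.n_cols;
  List Ws = p["W"], Us = p["U"], bs = p["b"];
  m.L = Ws.size();
  for (int l = 0; l < m.L; ++l) {
    m.W.push_back(Rcpp::as<mat>(Ws[l]));
    m.U.push_back(Rcpp::as<mat>(Us[l]));
    m.b.push_back(Rcpp::as<vec>(bs[l]));
  }
  m.H = m.U[0].n_cols;
  m.Why = Rcpp::as<mat>(p["Why"]);
  m.by = Rcpp::as<vec>(p["by"]);
  return m;
}

static List to_list(const GruModel &m) {
  List Ws(m.L), Us(m.L), bs(m.L);
  for (int l = 0; l < m.L; ++l) {
    Ws[l] = m.W[l];
    Us[l] = m.U[l];
    bs[l] = m.b[l];
  }
  return List::create(Rcpp::_["Emb"] = m.Emb, Rcpp::_["W"] = Ws,
                      Rcpp::_["U"] = Us, Rcpp::_["b"] = bs,
                      Rcpp::_["Why"] = m.Why, Rcpp::_["by"] = m.by);
}

static mat runif_mat(int r, int c, double s) {
  mat x(r, c);
  for (uword i = 0; i < x.n_elem; ++i) x(i) = (unif_rand() * 2.0 - 1.0) * s;
  return x;
}

// [[Rcpp::export]]
List cpp_gru_new(int vocab, int emb_dim, int hidden, int n_layers) {
  GruModel m;
  m.V = vocab;
  m.D = emb_dim;
  m.H = hidden;
  m.L = n_layers;
  m.Emb = runif_mat(emb_dim, vocab, 0.08);
  for (int l = 0; l < n_layers; ++l) {
    int din = l == 0 ? emb_dim : hidden;
    double sw = std::sqrt(6.0 / (din + hidden));
    double su = std::sqrt(6.0 / (2.0 * hidden));
    m.W.push_back(runif_mat(3 * hidden, din, sw));
    m.U.push_back(runif_mat(3 * hidden, hidden, su));
    m.b.push_back(zeros<vec>(3 * hidden));
  }
  m.Why = runif_mat(vocab, hidden, std::sqrt(6.0 / (hidden + vocab)));
  m.by = zeros<vec>(vocab);
  return to_list(m);
}

struct StepCache {
  mat hprev, z, r, n, hn_pre, x;  // x = layer input (post dropout)
};

static inline mat sigmoid(const mat &x) { return 1.0 / (1.0 + exp(-x)); }

// forward one timestep for one layer; h updated in place
static void gru_step(const GruModel &m, int l, const mat &x, mat &h,
                     StepCache *cache) {
  const int H = m.H;
  mat a = m.W[l] * x;
  a.each_col() += m.b[l];
  mat uh = m.U[l] * h;
  mat az = a.rows(0, H - 1) + uh.rows(0, H - 1);
  mat ar = a.rows(H, 2 * H - 1) + uh.rows(H, 2 * H - 1);
  mat z = sigmoid(az);
  mat r = sigmoid(ar);
  mat hn_pre = uh.rows(2 * H, 3 * H - 1);
  mat n = tanh(a.rows(2 * H, 3 * H - 1) + r % hn_pre);
  if (cache) {
    cache->hprev = h;
    cache->z = z;
    cache->r = r;
    cache->n = n;
    cache->hn_pre = hn_pre;
    cache->x = x;
  }
  h = (1.0 - z) % n + z % h;
}

struct Grads {
  mat Emb;
  std::vector<mat> W, U;
  std::vector<vec> b;
  mat Why;
  vec by;
};

static Grads zero_grads(const GruModel &m) {
  Grads g;
  g.Emb = zeros<mat>(m.D, m.V);
  for (int l = 0; l < m.L; ++l) {
    g.W.push_back(zeros<mat>(size(m.W[l])));
    g.U.push_back(zeros<mat>(size(m.U[l])));
    g.b.push_back(zeros<vec>(3 * m.H));
  }
  g.Why = zeros<mat>(size(m.Why));
  g.by = zeros<vec>(m.V);
  return g;
}

// batch forward (+ optional backward) over sequences laid out as an
// int matrix tokens (B x T); targets are tokens shifted left; positions
// with target == pad_id are masked out of the loss.
static double run_batch(GruModel &m, const imat &tokens, int pad_id,
                        double dropout, bool train, Grads *g) {
  const int B = tokens.n_rows;
  const int T = tokens.n_cols - 1;  // predict positions 1..T
  const int H = m.H, L = m.L;
  std::vector<std::vector<StepCache>> cache(
      L, std::vector<StepCache>(train ? T : 0));
  std::vector<mat> drop_mask(L - 1);
  std::vector<mat> h(L, zeros<mat>(H, B));
  std::vector<mat> probs(train ? T : 0);
  umat mask(B, T);
  double loss = 0.0;
  long n_tok = 0;

  if (train && dropout > 0) {
    for (int l = 0; l + 1 < L; ++l) {
      drop_mask[l] = mat(H, B * T);
      for (uword i = 0; i < drop_mask[l].n_elem; ++i)
        drop_mask[l](i) = unif_rand() < dropout ? 0.0 : 1.0 / (1.0 - dropout);
    }
  }

  for (int t = 0; t < T; ++t) {
    mat x(m.D, B);
    for (int bi = 0; bi < B; ++bi) x.col(bi) = m.Emb.col(tokens(bi, t));
    for (int l = 0; l < L; ++l) {
      gru_step(m, l, x, h[l], train ? &cache[l][t] : nullptr);
      x = h[l];
      if (l + 1 < L && train && dropout > 0)
        x %= drop_mask[l].cols(t * B, (t + 1) * B - 1);
    }
    mat logits = m.Why * h[L - 1];
    logits.each_col() += m.by;
    logits.each_row() -= max(logits, 0);
    mat p = exp(logits);
    p.each_row() /= sum(p, 0);
    for (int bi = 0; bi < B; ++bi) {
      int tgt = tokens(bi, t + 1);
      bool keep = tgt != pad_id;
      mask(bi, t) = keep;
      if (keep) {
        loss -= std::log(std::max(p(tgt, bi), 1e-12));
        ++n_tok;
      }
    }
    if (train) probs[t] = p;
  }
  if (n_tok == 0) return 0.0;
  loss /= n_tok;
  if (!train) return loss;

  std::vector<mat> dh(L, zeros<mat>(H, B));
  for (int t = T - 1; t >= 0; --t) {
    mat dlog = probs[t];
    for (int bi = 0; bi < B; ++bi) {
      if (mask(bi, t)) {
        dlog(tokens(bi, t + 1), bi) -= 1.0;
        dlog.col(bi) /= n_tok;
      } else {
        dlog.col(bi).zeros();
      }
    }
    const StepCache &ctop = cache[L - 1][t];
    mat htop = (1.0 - ctop.z) % ctop.n + ctop.z % ctop.hprev;
    g->Why += dlog * htop.t();
    g->by += sum(dlog, 1);
    dh[L - 1] += m.Why.t() * dlog;
    for (int l = L - 1; l >= 0; --l) {
      const StepCache &c = cache[l][t];
      mat dz = dh[l] % (c.hprev - c.n);
      mat dn = dh[l] % (1.0 - c.z);
      mat dan = dn % (1.0 - c.n % c.n);
      mat dr = dan % c.hn_pre;
      mat daz = dz % c.z % (1.0 - c.z);
      mat dar = dr % c.r % (1.0 - c.r);
      mat danr = dan % c.r;
      const int H1 = H - 1;
      g->W[l].rows(0, H1) += daz * c.x.t();
      g->W[l].rows(H, 2 * H - 1) += dar * c.x.t();
      g->W[l].rows(2 * H, 3 * H - 1) += dan * c.x.t();
      g->U[l].rows(0, H1) += daz * c.hprev.t();
      g->U[l].rows(H, 2 * H - 1) += dar * c.hprev.t();
      g->U[l].rows(2 * H, 3 * H - 1) += danr * c.hprev.t();
      g->b[l].subvec(0, H1) += sum(daz, 1);
      g->b[l].subvec(H, 2 * H - 1) += sum(dar, 1);
      g->b[l].subvec(2 * H, 3 * H - 1) += sum(dan, 1);
      mat dx = m.W[l].rows(0, H1).t() * daz +
               m.W[l].rows(H, 2 * H - 1).t() * dar +
               m.W[l].rows(2 * H, 3 * H - 1).t() * dan;
      dh[l] = dh[l] % c.z + m.U[l].rows(0, H1).t() * daz +
              m.U[l].rows(H, 2 * H - 1).t() * dar +
              m.U[l].rows(2 * H, 3 * H - 1).t() * danr;
      if (l > 0) {
        if (dropout > 0) dx %= drop_mask[l - 1].cols(t * B, (t + 1) * B - 1);
        dh[l - 1] += dx;
      } else {
        for (int bi = 0; bi < B; ++bi) g->Emb.col(tokens(bi, t)) += dx.col(bi);
      }
    }
  }
  return loss;
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Grads m_, v_;
};

static void adam_update(mat &p, mat &g, mat &mm, mat &vv, const Adam &a) {
  mm = a.b1 * mm + (1 - a.b1) * g;
  vv = a.b2 * vv + (1 - a.b2) * (g % g);
  double bc1 = 1 - std::pow(a.b1, a.t);
  double bc2 = 1 - std::pow(a.b2, a.t);
  p -= a.lr * (mm / bc1) / (sqrt(vv / bc2) + a.eps);
}

static void adam_step(GruModel &m, Grads &g, Adam &a, double clip) {
  double sq = accu(g.Emb % g.Emb) + accu(g.Why % g.Why) + accu(g.by % g.by);
  for (int l = 0; l < m.L; ++l)
    sq += accu(g.W[l] % g.W[l]) + accu(g.U[l] % g.U[l]) + accu(g.b[l] % g.b[l]);
  double nrm = std::sqrt(sq);
  if (clip > 0 && nrm > clip) {
    double s = clip / nrm;
    g.Emb *= s;
    g.Why *= s;
    g.by *= s;
    for (int l = 0; l < m.L; ++l) {
      g.W[l] *= s;
      g.U[l] *= s;
      g.b[l] *= s;
    }
  }
  ++a.t;
  adam_update(m.Emb, g.Emb, a.m_.Emb, a.v_.Emb, a);
  adam_update(m.Why, g.Why, a.m_.Why, a.v_.Why, a);
  {
    mat gb(g.by), mb(a.m_.by), vb(a.v_.by), pb(m.by);
    adam_update(pb, gb, mb, vb, a);
    m.by = pb;
    a.m_.by = mb;
    a.v_.by = vb;
  }
  for (int l = 0; l < m.L; ++l) {
    adam_update(m.W[l], g.W[l], a.m_.W[l], a.v_.W[l], a);
    adam_update(m.U[l], g.U[l], a.m_.U[l], a.v_.U[l], a);
    mat gb(g.b[l]), mb(a.m_.b[l]), vb(a.v_.b[l]), pb(m.b[l]);
    adam_update(pb, gb, mb, vb, a);
    m.b[l] = pb;
    a.m_.b[l] = mb;
    a.v_.b[l] = vb;
  }
}

static imat pad_block(const std::vector<std::vector<int>> &seqs,
                      const std::vector<int> &pick, int pad_id) {
  int B = pick.size();
  int T = 0;
  for (int i : pick) T = std::max<int>(T, seqs[i].size());
  imat out(B, T);
  out.fill(pad_id);
  for (int bi = 0; bi < B; ++bi)
    for (size_t t = 0; t < seqs[pick[bi]].size(); ++t)
      out(bi, t) = seqs[pick[bi]][t];
  return out;
}

// [[Rcpp::export]]
List cpp_gru_train(List params, List seqs_, int pad_id, int epochs,
                   int batch_size, double lr, double dropout,
                   double val_frac, double clip = 5.0) {
  GruModel m = from_list(params);
  const int n = seqs_.size();
  std::vector<std::vector<int>> seqs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs_[i];
    seqs[i] = std::vector<int>(s.begin(), s.end());
  }
  // seeded shuffle (R RNG) then tail split for validation
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = static_cast<int>(unif_rand() * (i + 1));
    std::swap(ord[i], ord[j]);
  }
  int n_val = static_cast<int>(std::floor(n * val_frac));
  int n_tr = n - n_val;
  if (n_tr < 1) stop("no training sequences left after validation split");
  std::vector<int> tr(ord.begin(), ord.begin() + n_tr);
  std::vector<int> va(ord.begin() + n_tr, ord.end());

  Adam adam;
  adam.lr = lr;
  adam.m_ = zero_grads(m);
  adam.v_ = zero_grads(m);
  NumericVector train_loss(epochs), val_loss(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n_tr - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      std::swap(tr[i], tr[j]);
    }
    double ep_loss = 0.0;
    int n_batches = 0;
    for (int s = 0; s < n_tr; s += batch_size) {
      std::vector<int> pick(tr.begin() + s,
                            tr.begin() + std::min(n_tr, s + batch_size));
      imat tok = pad_block(seqs, pick, pad_id);
      Grads g = zero_grads(m);
      double l = run_batch(m, tok, pad_id, dropout, true, &g);
      if (!std::isfinite(l)) stop("non-finite training loss");
      adam_step(m, g, adam, clip);
      ep_loss += l;
      ++n_batches;
    }
    train_loss[ep] = ep_loss / std::max(1, n_batches);
    if (n_val > 0) {
      imat tok = pad_block(seqs, va, pad_id);
      val_loss[ep] = run_batch(m, tok, pad_id, 0.0, false, nullptr);
    } else {
      val_loss[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(Rcpp::_["params"] = to_list(m),
                      Rcpp::_["train_loss"] = train_loss,
                      Rcpp::_["val_loss"] = val_loss);
}

// ---- inference -------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_gru_handle(List params) {
  GruModel *m = new GruModel(from_list(params));
  Rcpp::XPtr<GruModel> ptr(m, true);
  return ptr;
}

static vec forward_prefix(const GruModel &m, const IntegerVector &prefix,
                          std::vector<mat> &h) {
  h.assign(m.L, zeros<mat>(m.H, 1));
  vec p;
  for (int t = 0; t < prefix.size(); ++t) {
    if (prefix[t] < 0 || prefix[t] >= m.V) stop("token id out of vocabulary");
    mat x = m.Emb.col(prefix[t]);
    for (int l = 0; l < m.L; ++l) {
      gru_step(m, l, x, h[l], nullptr);
      x = h[l];
    }
  }
  vec logits = m.Why * h[m.L - 1].col(0) + m.by;
  logits -= logits.max();
  p = exp(logits);
  p /= accu(p);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_gru_probs(SEXP ptr_, IntegerVector prefix) {
  Rcpp::XPtr<GruModel> ptr(ptr_);
  std::vector<mat> h;
  vec p = forward_prefix(*ptr, prefix, h);
  return NumericVector(p.begin(), p.end());
}

static int draw(const vec &p, double temperature) {
  if (temperature <= 0) return p.index_max();
  vec q;
  if (temperature == 1.0) {
    q = p;
  } else {
    q = pow(p, 1.0 / temperature);
    q /= accu(q);
  }
  double u = unif_rand(), c = 0.0;
  for (uword i = 0; i < q.n_elem; ++i) {
    c += q(i);
    if (u <= c) return i;
  }
  return q.n_elem - 1;
}

// Extend `prefix` token-by-token until `end_id` or `max_new` additional
// tokens; returns only the newly sampled tokens (0-based ids).
// [[Rcpp::export]]
IntegerVector cpp_gru_sample(SEXP ptr_, IntegerVector prefix, int max_new,
                             double temperature, int end_id) {
  Rcpp::XPtr<GruModel> ptr(ptr_);
  const GruModel &m = *ptr;
  std::vector<mat> h;
  vec p = forward_prefix(m, prefix, h);
  std::vector<int> out;
  for (int step = 0; step < max_new; ++step) {
    int tok = draw(p, temperature);
    out.push_back(tok);
    if (tok == end_id) break;
    mat x = m.Emb.col(tok);
    for (int l = 0; l < m.L; ++l) {
      gru_step(m, l, x, h[l], nullptr);
      x = h[l];
    }
    vec logits = m.Why * h[m.L - 1].col(0) + m.by;
    logits -= logits.max();
    p = exp(logits);
    p /= accu(p);
  }
  return IntegerVector(out.begin(), out.end());
}
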