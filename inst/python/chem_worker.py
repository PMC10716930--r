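"""Persistent RDKit worker.

Speaks a line protocol on stdin/stdout: one JSON request per line
({"id": n, "op": str, "args": {...}}), one JSON response per line
({"id": n, "ok": bool, "result"/"error": ...}).  All chemistry that the
R package does not own (parsing, standardization, identifiers,
descriptors, fingerprints, SMARTS matching) funnels through here so a
single interpreter survives across calls.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Descriptors, QED, rdMolDescriptors
from rdkit.Chem import rdMHFPFingerprint
from rdkit.Chem.MolStandardize import rdMolStandardize
from rdkit.Chem.Scaffolds import MurckoScaffold
from rdkit.Chem import RDConfig
import os

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

RDLogger.DisableLog("rdApp.*")

_uncharger = rdMolStandardize.Uncharger()
_mhfp_encoders = {}


def _mol(smiles):
    if not isinstance(smiles, str) or smiles == "":
        return None
    return Chem.MolFromSmiles(smiles)


def _has_carbon(mol):
    return any(a.GetAtomicNum() == 6 for a in mol.GetAtoms())


def _standardize_one(smiles):
    """ChEMBL-pipeline-style: cleanup, keep largest organic fragment,
    neutralize.  Returns (canonical_smiles, inchikey_nostereo, error)."""
    mol = _mol(smiles)
    if mol is None:
        return None, None, "InvalidSmiles"
    try:
        mol = rdMolStandardize.Cleanup(mol)
        if mol is None or mol.GetNumAtoms() == 0:
            return None, None, "StandardizationFailure"
        mol = rdMolStandardize.FragmentParent(mol)
        if mol is None or mol.GetNumAtoms() == 0 or not _has_carbon(mol):
            return None, None, "StandardizationFailure"
        mol = _uncharger.uncharge(mol)
        can = Chem.MolToSmiles(mol)
        key = _inchikey_nostereo_mol(mol)
        if key is None:
            return None, None, "KeyGenerationFailure"
        return can, key, None
    except Exception as exc:  # pragma: no cover - defensive
        return None, None, "StandardizationFailure: %s" % exc


def _inchikey_nostereo_mol(mol):
    m = Chem.Mol(mol)
    Chem.RemoveStereochemistry(m)
    try:
        key = Chem.MolToInchiKey(m)
    except Exception:
        return None
    return key or None


def op_ping(args):
    return "pong"


def op_parse(args):
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append({"valid": False})
        else:
            out.append(
                {
                    "valid": True,
                    "canonical_smiles": Chem.MolToSmiles(mol),
                    "n_heavy_atoms": mol.GetNumHeavyAtoms(),
                }
            )
    return out


def op_standardize(args):
    out = []
    for s in args["smiles"]:
        can, key, err = _standardize_one(s)
        out.append(
            {
                "ok": err is None,
                "canonical_smiles": can,
                "inchikey_nostereo": key,
                "error": err,
            }
        )
    return out


def op_parse_key(args):
    """Canonical SMILES + stereo-free InChIKey without the standardization
    pass; for inputs already known to be single-component and neutral."""
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append({"valid": False})
            continue
        key = _inchikey_nostereo_mol(mol)
        out.append(
            {
                "valid": key is not None,
                "canonical_smiles": Chem.MolToSmiles(mol),
                "inchikey_nostereo": key,
            }
        )
    return out


def op_inchikey(args):
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        out.append(None if mol is None else _inchikey_nostereo_mol(mol))
    return out


def _descriptors_one(mol):
    ri = mol.GetRingInfo()
    rings = ri.AtomRings()
    try:
        scaffold = MurckoScaffold.MurckoScaffoldSmiles(mol=mol)
    except Exception:
        scaffold = ""
    return {
        "mol_weight": Descriptors.MolWt(mol),
        "slogp": Descriptors.MolLogP(mol),
        "n_atoms": mol.GetNumAtoms(onlyExplicit=False),
        "n_heavy_atoms": mol.GetNumHeavyAtoms(),
        "n_aromatic_rings": rdMolDescriptors.CalcNumAromaticRings(mol),
        "fraction_csp3": rdMolDescriptors.CalcFractionCSP3(mol),
        "hbd": rdMolDescriptors.CalcNumLipinskiHBD(mol),
        "hba": rdMolDescriptors.CalcNumLipinskiHBA(mol),
        "qed": QED.qed(mol),
        "sa_score": sascorer.calculateScore(mol),
        "max_ring_size": max((len(r) for r in rings), default=0),
        "n_radical_electrons": sum(
            a.GetNumRadicalElectrons() for a in mol.GetAtoms()
        ),
        "murcko_scaffold": scaffold,
    }


def op_descriptors(args):
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append({"error": "InvalidSmiles"})
            continue
        try:
            out.append(_descriptors_one(mol))
        except Exception as exc:
            out.append({"error": "DescriptorFailure: %s" % exc})
    return out


def _mhfp_encoder(seed):
    if seed not in _mhfp_encoders:
        _mhfp_encoders[seed] = rdMHFPFingerprint.MHFPEncoder(2048, seed)
    return _mhfp_encoders[seed]


def op_fingerprint(args):
    kind = args["kind"]
    seed = int(args.get("seed", 42))
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append(None)
            continue
        if kind in ("morgan_r2", "morgan_r3"):
            radius = 2 if kind == "morgan_r2" else 3
            bv = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=2048)
            out.append(list(bv.GetOnBits()))
        elif kind == "mhfp6":
            # signed int32 view so R's integer type holds the values
            out.append(
                [
                    int(v) - 2**32 if v >= 2**31 else int(v)
                    for v in _mhfp_encoder(seed).EncodeMol(mol)
                ]
            )
        else:
            raise ValueError("UnsupportedKind: %s" % kind)
    return out


def op_fingerprint_file(args):
    """Bulk fingerprints written as little-endian int32 binary to a file
    (row per molecule: 64 packed words for morgan, 2048 minhash values for
    mhfp6).  Avoids JSON transport for large reference sets.  Returns the
    number of molecules written; unparseable SMILES are an error here
    because callers pass pre-validated sets."""
    import array

    kind = args["kind"]
    path = args["path"]
    seed = int(args.get("seed", 42))
    radius = 2 if kind == "morgan_r2" else 3
    n = 0
    if kind == "mhfp6":
        # bulk-encode in C++; uint32 bytes equal the int32 view R reads
        enc = _mhfp_encoder(seed)
        fps = enc.EncodeSmilesBulk(list(args["smiles"]))
        with open(path, "wb") as fh:
            for s, f in zip(args["smiles"], fps):
                if len(f) != 2048:
                    raise ValueError("InvalidSmiles: %s" % s)
                array.array("I", f).tofile(fh)
                n += 1
        return n
    with open(path, "wb") as fh:
        for s in args["smiles"]:
            mol = _mol(s)
            if mol is None:
                raise ValueError("InvalidSmiles: %s" % s)
            bv = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=2048)
            words = [0] * 64
            for b in bv.GetOnBits():
                words[b // 32] |= 1 << (b % 32)
            array.array("I", words).tofile(fh)
            n += 1
    return n


def op_match_smarts(args):
    patterns = [Chem.MolFromSmarts(p) for p in args["patterns"]]
    if any(p is None for p in patterns):
        bad = [
            args["patterns"][i] for i, p in enumerate(patterns) if p is None
        ]
        raise ValueError("InvalidSmarts: %s" % ", ".join(bad))
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append(None)
        else:
            out.append([bool(mol.HasSubstructMatch(p)) for p in patterns])
    return out


def op_atom_audit(args):
    """Element / isotope / ring audit used by the corpus curation stages."""
    allowed = set(args["allowed_elements"])
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append({"parseable": False})
            continue
        symbols = {a.GetSymbol() for a in mol.GetAtoms()}
        out.append(
            {
                "parseable": True,
                "elements_ok": symbols.issubset(allowed),
                "has_isotope": any(
                    a.GetIsotope() != 0 for a in mol.GetAtoms()
                ),
                "n_rings": mol.GetRingInfo().NumRings(),
                "n_components": len(Chem.GetMolFrags(mol)),
            }
        )
    return out


def op_murcko(args):
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append(None)
            continue
        try:
            out.append(MurckoScaffold.MurckoScaffoldSmiles(mol=mol))
        except Exception:
            out.append("")
    return out


def op_eval_generated(args):
    """One-shot evaluation of a proposed SMILES for the generator loop:
    parse, standardize, and exactly the descriptors the generation filters
    and rewards need, in one trip."""
    patterns = [Chem.MolFromSmarts(p) for p in args.get("patterns", [])]
    out = []
    for s in args["smiles"]:
        mol = _mol(s)
        if mol is None:
            out.append({"parse_valid": False})
            continue
        can, key, err = _standardize_one(s)
        if err is not None:
            out.append({"parse_valid": False})
            continue
        smol = Chem.MolFromSmiles(can)
        rings = smol.GetRingInfo().AtomRings()
        rec = {
            "parse_valid": True,
            "canonical_smiles": can,
            "inchikey_nostereo": key,
            "mol_weight": Descriptors.MolWt(smol),
            "slogp": Descriptors.MolLogP(smol),
            "hbd": rdMolDescriptors.CalcNumLipinskiHBD(smol),
            "hba": rdMolDescriptors.CalcNumLipinskiHBA(smol),
            "sa_score": sascorer.calculateScore(smol),
            "max_ring_size": max((len(r) for r in rings), default=0),
            "n_radical_electrons": sum(
                a.GetNumRadicalElectrons() for a in smol.GetAtoms()
            ),
            "blacklist_hit": any(
                smol.HasSubstructMatch(p) for p in patterns
            ),
        }
        out.append(rec)
    return out


OPS = {
    "ping": op_ping,
    "parse": op_parse,
    "standardize": op_standardize,
    "inchikey": op_inchikey,
    "parse_key": op_parse_key,
    "descriptors": op_descriptors,
    "fingerprint": op_fingerprint,
    "fingerprint_file": op_fingerprint_file,
    "match_smarts": op_match_smarts,
    "atom_audit": op_atom_audit,
    "murcko": op_murcko,
    "eval_generated": op_eval_generated,
}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            rid = req.get("id")
            op = OPS.get(req["op"])
            if op is None:
                resp = {"id": rid, "ok": False, "error": "UnknownOp"}
            else:
                resp = {"id": rid, "ok": True, "result": op(req.get("args", {}))}
        except Exception as exc:
            resp = {"id": req.get("id") if isinstance(req, dict) else None,
                    "ok": False, "error": str(exc)}
        sys.stdout.write(json.dumps(resp) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
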