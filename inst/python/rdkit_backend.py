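"""RDKit bridge for simmapr.

Reads one JSON request on stdin, writes one JSON response on stdout.
All chemistry that simmapr delegates to the toolkit goes through here:
molecule parsing/sanitization, canonical SMILES, 2D layout, SMARTS
matching, and the raw fingerprint/bit-environment reports from which the
R side builds its sparse fingerprints and atom-ownership tables.

The protocol is deliberately dumb: every request is a batch, every
response is plain JSON, and nothing is cached here. Indices are 0-based
in this file; the R side converts to 1-based at the boundary.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def _mol_from(text, fmt):
    if fmt == "smiles":
        return Chem.MolFromSmiles(text)
    if fmt == "molblock":
        return Chem.MolFromMolBlock(text)
    raise ValueError("unknown format: %r" % fmt)


def _mol_payload(mol, want_coords):
    atoms = []
    for a in mol.GetAtoms():
        atoms.append(
            {
                "element": a.GetSymbol(),
                "aromatic": a.GetIsAromatic(),
                "charge": a.GetFormalCharge(),
                "n_h": a.GetTotalNumHs(),
                "degree": a.GetDegree(),
            }
        )
    bonds = []
    for b in mol.GetBonds():
        bonds.append(
            {
                "a": b.GetBeginAtomIdx(),
                "b": b.GetEndAtomIdx(),
                "order": b.GetBondTypeAsDouble(),
                "aromatic": b.GetIsAromatic(),
            }
        )
    out = {
        "ok": True,
        "smiles": Chem.MolToSmiles(mol),
        "atoms": atoms,
        "bonds": bonds,
    }
    if want_coords:
        AllChem.Compute2DCoords(mol)
        conf = mol.GetConformer()
        out["coords"] = [
            [conf.GetAtomPosition(i).x, conf.GetAtomPosition(i).y]
            for i in range(mol.GetNumAtoms())
        ]
    return out


def op_parse(req):
    res = []
    for entry in req["molecules"]:
        mol = _mol_from(entry["text"], entry.get("format", "smiles"))
        if mol is None:
            res.append({"ok": False, "error": "unparseable %s: %r"
                        % (entry.get("format", "smiles"), entry["text"])})
        else:
            res.append(_mol_payload(mol, req.get("want_coords", False)))
    return res


def _ap_pairs(mol, max_path_length):
    """All heavy-atom pairs (i, j, topological distance, pair code)."""
    dm = Chem.GetDistanceMatrix(mol)
    codes = [rdMolDescriptors.GetAtomPairAtomCode(a) for a in mol.GetAtoms()]
    n = mol.GetNumAtoms()
    pairs = []
    for i in range(n):
        for j in range(i + 1, n):
            d = int(dm[i][j])
            if 1 <= d <= max_path_length:
                pairs.append(
                    [i, j, d, rdMolDescriptors.GetAtomPairCode(codes[i], codes[j], d)]
                )
    return pairs


def _morgan_bitinfo(mol, radius, folded_size, use_features):
    """Bit-environment report: one [bit, center, radius] per environment."""
    info = {}
    if folded_size is None:
        rdMolDescriptors.GetMorganFingerprint(
            mol, radius, bitInfo=info, useFeatures=use_features
        )
    else:
        rdMolDescriptors.GetMorganFingerprintAsBitVect(
            mol, radius, nBits=folded_size, bitInfo=info, useFeatures=use_features
        )
    envs = []
    for bit, occs in info.items():
        for center, rad in occs:
            envs.append([int(bit), int(center), int(rad)])
    return envs


def op_fingerprints(req):
    res = []
    for smi in req["molecules"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            res.append({"ok": False, "error": "unparseable smiles: %r" % smi})
            continue
        entry = {"ok": True, "flavors": []}
        for fl in req["flavors"]:
            kind = fl["kind"]
            if kind == "ap":
                entry["flavors"].append(
                    {"pairs": _ap_pairs(mol, int(fl.get("max_path_length", 30)))}
                )
            elif kind in ("morgan", "feat_morgan"):
                folded = fl.get("folded_size")
                entry["flavors"].append(
                    {
                        "envs": _morgan_bitinfo(
                            mol,
                            int(fl.get("radius", 2)),
                            int(folded) if folded else None,
                            kind == "feat_morgan",
                        )
                    }
                )
            else:
                raise ValueError("unknown fingerprint kind: %r" % kind)
        res.append(entry)
    return res


def op_match(req):
    pats = []
    for p in req["smarts"]:
        q = Chem.MolFromSmarts(p)
        if q is None:
            raise ValueError("invalid SMARTS: %r" % p)
        pats.append(q)
    res = []
    for smi in req["molecules"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            res.append({"ok": False, "error": "unparseable smiles: %r" % smi})
            continue
        hits = []
        for q in pats:
            hits.append([list(m) for m in mol.GetSubstructMatches(q)])
        res.append({"ok": True, "matches": hits})
    return res


OPS = {"parse": op_parse, "fingerprints": op_fingerprints, "match": op_match}


def main():
    req = json.load(sys.stdin)
    try:
        out = {"ok": True, "result": OPS[req["op"]](req)}
    except Exception as exc:  # surfaced as an R condition by the caller
        out = {"ok": False, "error": "%s: %s" % (type(exc).__name__, exc)}
    json.dump(out, sys.stdout)


if __name__ == "__main__":
    main()
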