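"""RDKit bridge for the smigen R package.

Runs either as a persistent worker (``serve``: one JSON request per line on
stdin, one JSON response per line on stdout) or one-shot (``batch IN OUT``).
All chemistry used by the R side funnels through here: strict SMILES
validity (parse + sanitize), canonicalization, molecular descriptors,
functional-group SMARTS matching and Morgan fingerprints.
"""

import sys
import json

from rdkit import Chem, RDLogger
from rdkit.Chem import Descriptors, Crippen, Lipinski
from rdkit.Chem import rdFingerprintGenerator
from rdkit import DataStructs

RDLogger.DisableLog("rdApp.*")

# Functional-group SMARTS defaults; the R side passes its own (config-visible)
# patterns with every descriptor request, these are only a fallback.
DEFAULT_PATTERNS = {
    "fg_oh": "[OX2H][#6]",
    "fg_ester": "[#6]C(=O)O[#6]",
    "fg_cooh": "C(=O)[OX2H1]",
    "fg_nh2": "[NX3;H2;!$(NC=O)]",
}

_pattern_cache = {}


def _smarts(p):
    m = _pattern_cache.get(p)
    if m is None:
        m = Chem.MolFromSmarts(p)
        if m is None:
            raise ValueError("bad SMARTS pattern: %s" % p)
        _pattern_cache[p] = m
    return m


def _mol(smiles):
    # None unless parse + sanitize succeed; the empty string parses to an
    # empty mol in RDKit but is not a molecule for our purposes
    if not smiles or not smiles.strip():
        return None
    return Chem.MolFromSmiles(smiles)


def task_parse(req):
    valid, canonical = [], []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            valid.append(False)
            canonical.append(None)
        else:
            valid.append(True)
            canonical.append(Chem.MolToSmiles(m))
    return {"valid": valid, "canonical": canonical}


def _ring_counts(m):
    arom = nonarom = 0
    for ring in m.GetRingInfo().AtomRings():
        if all(m.GetAtomWithIdx(i).GetIsAromatic() for i in ring):
            arom += 1
        else:
            nonarom += 1
    return arom, nonarom


def task_descriptors(req):
    patterns = req.get("patterns") or DEFAULT_PATTERNS
    cols = {
        k: []
        for k in (
            "valid canonical logp mol_weight hba hbd rot_bonds "
            "aromatic_rings non_aromatic_rings heavy_atoms "
            "fg_oh fg_ester fg_cooh fg_nh2"
        ).split()
    }
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            cols["valid"].append(False)
            for k in cols:
                if k != "valid":
                    cols[k].append(None)
            continue
        arom, nonarom = _ring_counts(m)
        cols["valid"].append(True)
        cols["canonical"].append(Chem.MolToSmiles(m))
        cols["logp"].append(Crippen.MolLogP(m))
        cols["mol_weight"].append(Descriptors.MolWt(m))
        cols["hba"].append(Lipinski.NumHAcceptors(m))
        cols["hbd"].append(Lipinski.NumHDonors(m))
        cols["rot_bonds"].append(Lipinski.NumRotatableBonds(m))
        cols["aromatic_rings"].append(arom)
        cols["non_aromatic_rings"].append(nonarom)
        cols["heavy_atoms"].append(m.GetNumHeavyAtoms())
        for key in ("fg_oh", "fg_ester", "fg_cooh", "fg_nh2"):
            cols[key].append(bool(m.HasSubstructMatch(_smarts(patterns[key]))))
    return cols


def _fpgen(radius, n_bits):
    return rdFingerprintGenerator.GetMorganGenerator(
        radius=int(radius), fpSize=int(n_bits)
    )


def task_fingerprint(req):
    gen = _fpgen(req.get("radius", 2), req.get("n_bits", 1024))
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            fp = gen.GetFingerprint(m)
            out.append([int(i) for i in fp.GetOnBits()])
    return {"bits": out}


def task_tanimoto(req):
    # independent similarity oracle: RDKit's own Tanimoto on two molecules
    gen = _fpgen(req.get("radius", 2), req.get("n_bits", 1024))
    ma, mb = _mol(req["a"]), _mol(req["b"])
    if ma is None or mb is None:
        raise ValueError("tanimoto: invalid SMILES input")
    sim = DataStructs.TanimotoSimilarity(gen.GetFingerprint(ma), gen.GetFingerprint(mb))
    return {"sim": sim}


TASKS = {
    "parse": task_parse,
    "descriptors": task_descriptors,
    "fingerprint": task_fingerprint,
    "tanimoto": task_tanimoto,
    "ping": lambda req: {"ok": True},
}


def handle(req):
    task = req.get("task")
    if task == "quit":
        return None
    try:
        resp = TASKS[task](req)
        resp["id"] = req.get("id")
    except Exception as exc:  # report, never kill the worker
        resp = {"id": req.get("id"), "error": str(exc)}
    return resp


def serve():
    for line in sys.stdin:
        if not line.strip():
            continue
        resp = handle(json.loads(line))
        if resp is None:
            break
        sys.stdout.write(json.dumps(resp) + "\n")
        sys.stdout.flush()


def batch(path_in, path_out):
    with open(path_in) as fh:
        req = json.load(fh)
    resp = handle(req)
    with open(path_out, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    if len(sys.argv) >= 2 and sys.argv[1] == "serve":
        serve()
    elif len(sys.argv) >= 4 and sys.argv[1] == "batch":
        batch(sys.argv[2], sys.argv[3])
    else:
        sys.stderr.write("usage: rdkit_bridge.py serve | batch IN OUT\n")
        sys.exit(2)
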