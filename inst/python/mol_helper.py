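"""Batched RDKit helper: reads a JSON request, writes a JSON response.

Usage: python mol_helper.py <mode> <infile> <outfile>
Modes:
  mols      - parse + featurize a SMILES batch (atoms, bonds, BRICS fragments,
              fragment descriptors, Murcko scaffold, functional-group matches)
  recombine - enumerate new molecules by BRICS recombination of a fragment pool
"""
import sys, json, random

from rdkit import Chem, RDLogger
from rdkit.Chem import BRICS, MACCSkeys, rdMolDescriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

HALOGENS = {"F", "Cl", "Br", "I"}


def brics_label(lab):
    # '7a'/'7b' are sub-labels of link class 7
    return int(str(lab).rstrip("ab"))


def atom_table(mol):
    return {
        "symbol": [a.GetSymbol() for a in mol.GetAtoms()],
        "degree": [a.GetDegree() for a in mol.GetAtoms()],
        "charge": [a.GetFormalCharge() for a in mol.GetAtoms()],
        "chiral": [str(a.GetChiralTag()) for a in mol.GetAtoms()],
        "numh": [a.GetTotalNumHs() for a in mol.GetAtoms()],
        "hybrid": [str(a.GetHybridization()) for a in mol.GetAtoms()],
        "aromatic": [int(a.GetIsAromatic()) for a in mol.GetAtoms()],
        "mass": [a.GetMass() for a in mol.GetAtoms()],
    }


def bond_table(mol):
    t = {"a": [], "b": [], "type": [], "conj": [], "ring": [], "stereo": []}
    for b in mol.GetBonds():
        t["a"].append(b.GetBeginAtomIdx())
        t["b"].append(b.GetEndAtomIdx())
        t["type"].append(str(b.GetBondType()))
        t["conj"].append(int(b.GetIsConjugated()))
        t["ring"].append(int(b.IsInRing()))
        t["stereo"].append(str(b.GetStereo()))
    return t


def frag_descriptor(frag):
    elems = {"C": 0, "N": 0, "O": 0, "S": 0, "P": 0, "hal": 0, "other": 0}
    for a in frag.GetAtoms():
        s = a.GetSymbol()
        if s in elems:
            elems[s] += 1
        elif s in HALOGENS:
            elems["hal"] += 1
        else:
            elems["other"] += 1
    return {
        "maccs": [int(i) for i in MACCSkeys.GenMACCSKeys(frag).GetOnBits()],
        "elems": [elems[k] for k in ("C", "N", "O", "S", "P", "hal", "other")],
        "tpsa": rdMolDescriptors.CalcTPSA(frag),
        "heavy": frag.GetNumHeavyAtoms(),
        "rings": rdMolDescriptors.CalcNumRings(frag),
        "hbd": rdMolDescriptors.CalcNumHBD(frag),
        "hba": rdMolDescriptors.CalcNumHBA(frag),
    }


def brics_parts(mol):
    """Fragment membership (partition of heavy atoms), cleaved-bond edges with
    BRICS link labels, and per-fragment descriptors (cut ends capped with H)."""
    bonds = []
    for (i, j), (la, lb) in BRICS.FindBRICSBonds(mol):
        bidx = mol.GetBondBetweenAtoms(i, j).GetIdx()
        bonds.append((bidx, i, j, brics_label(la), brics_label(lb)))
    if not bonds:
        return [list(range(mol.GetNumAtoms()))], {"u": [], "v": [], "la": [], "lb": []}, [
            frag_descriptor(mol)]
    broken = Chem.FragmentOnBonds(mol, [b[0] for b in bonds], addDummies=False)
    mapping = []
    frag_mols = Chem.GetMolFrags(broken, asMols=True, sanitizeFrags=True,
                                 fragsMolAtomMapping=mapping)
    members = [sorted(int(i) for i in m) for m in mapping]
    atom2frag = {}
    for fi, mem in enumerate(members):
        for ai in mem:
            atom2frag[ai] = fi
    edges = {"u": [], "v": [], "la": [], "lb": []}
    for _, i, j, la, lb in bonds:
        edges["u"].append(atom2frag[i])
        edges["v"].append(atom2frag[j])
        edges["la"].append(la)
        edges["lb"].append(lb)
    descs = []
    for fm in frag_mols:
        try:
            descs.append(frag_descriptor(fm))
        except Exception:
            descs.append(None)
    return members, edges, descs


def fg_matches(mol, patterns):
    out = {"gid": [], "atoms": []}
    for gid, pat in patterns:
        if pat is None:
            continue
        seen = set()
        hits = []
        for match in mol.GetSubstructMatches(pat, uniquify=True, maxMatches=500):
            key = frozenset(match)
            if key in seen:
                continue
            seen.add(key)
            hits.append(sorted(int(i) for i in match))
        for atoms in sorted(hits):
            out["gid"].append(gid)
            out["atoms"].append(atoms)
    return out


def do_mols(req):
    patterns = []
    for k, entry in enumerate(req.get("fg", [])):
        patterns.append((k + 1, Chem.MolFromSmarts(entry["smarts"])))
    mols = []
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi) if smi else None
        if mol is None or mol.GetNumHeavyAtoms() == 0:
            mols.append({"input": smi, "ok": False,
                         "error": "unparseable or empty SMILES"})
            continue
        members, edges, descs = brics_parts(mol)
        rec = {
            "input": smi,
            "ok": True,
            "canonical": Chem.MolToSmiles(mol),
            "scaffold": MurckoScaffold.MurckoScaffoldSmiles(mol=mol),
            "atoms": atom_table(mol),
            "bonds": bond_table(mol),
            "frags": members,
            "frag_edges": edges,
            "frag_desc": descs,
        }
        if patterns:
            rec["fg"] = fg_matches(mol, patterns)
        mols.append(rec)
    return {"mols": mols}


def do_recombine(req):
    rng = random.Random(int(req.get("seed", 0)))
    random.seed(int(req.get("seed", 0)))
    max_heavy = int(req.get("max_heavy", 40))
    n = int(req["n"])
    pool = set()
    for smi in req["smiles"]:
        mol = Chem.MolFromSmiles(smi)
        if mol is None:
            continue
        try:
            pool.update(BRICS.BRICSDecompose(mol, returnMols=False))
        except Exception:
            continue
    frags = sorted(pool)
    rng.shuffle(frags)
    frags = [Chem.MolFromSmiles(f) for f in frags[:150]]
    frags = [f for f in frags if f is not None]
    known = {Chem.MolToSmiles(Chem.MolFromSmiles(s)) for s in req["smiles"]
             if Chem.MolFromSmiles(s) is not None}
    out, tried = [], 0
    gen = BRICS.BRICSBuild(frags, scrambleReagents=False, maxDepth=2)
    for mol in gen:
        tried += 1
        if tried > 40 * n:
            break
        try:
            Chem.SanitizeMol(mol)
        except Exception:
            continue
        if mol.GetNumHeavyAtoms() > max_heavy or mol.GetNumHeavyAtoms() < 3:
            continue
        smi = Chem.MolToSmiles(mol)
        if smi in known:
            continue
        known.add(smi)
        out.append(smi)
        if len(out) >= n:
            break
    return {"smiles": out}


def do_check_smarts(req):
    return {"ok": [Chem.MolFromSmarts(s) is not None for s in req["smarts"]]}


def do_subfrag(req):
    """Descriptor for an atom subset of a parent molecule, cut ends capped
    with implicit hydrogens."""
    out = []
    for item in req["items"]:
        mol = Chem.MolFromSmiles(item["smiles"])
        keep = set(int(i) for i in item["atoms"])
        if mol is None or not keep:
            out.append(None)
            continue
        try:
            rw = Chem.RWMol(mol)
            for idx in sorted(range(mol.GetNumAtoms()), reverse=True):
                if idx not in keep:
                    rw.RemoveAtom(idx)
            sub = rw.GetMol()
            Chem.SanitizeMol(sub)
            out.append(frag_descriptor(sub))
        except Exception:
            out.append(None)
    return {"desc": out}


def main(argv):
    mode, infile, outfile = argv[1], argv[2], argv[3]
    with open(infile) as fh:
        req = json.load(fh)
    if mode == "mols":
        res = do_mols(req)
    elif mode == "recombine":
        res = do_recombine(req)
    elif mode == "check_smarts":
        res = do_check_smarts(req)
    elif mode == "subfrag":
        res = do_subfrag(req)
    else:
        raise SystemExit("unknown mode: " + mode)
    with open(outfile, "w") as fh:
        json.dump(res, fh)


if __name__ == "__main__":
    main(sys.argv)
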