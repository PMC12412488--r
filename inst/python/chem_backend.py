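"""RDKit backend for tripod3d.

Reads a JSON request from argv[1], writes a JSON response to argv[2].
Batched: one process handles a whole molecule list, so RDKit import cost
is paid once per dataset, not per molecule.

Request:  {"op": "parse" | "conformer" | "stereo" | "scaffold",
           "molecules": [{"id": ..., "smiles": ...} | {"id": ..., "sdf": ...}],
           "n_candidates": int, "seed": int,         # conformer
           "generic": bool}                          # scaffold
Response: {"results": [{"id": ..., "error": str | null, ...}]}

All numeric output is plain JSON; coordinates in Angstrom.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
from rdkit.Chem.EnumerateStereoisomers import (EnumerateStereoisomers,
                                               StereoEnumerationOptions)
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

HYB = {"S": "s", "SP": "sp", "SP2": "sp2", "SP3": "sp3",
       "SP3D": "sp3d", "SP3D2": "sp3d2"}
CHI = {"CHI_UNSPECIFIED": "none",
       "CHI_TETRAHEDRAL_CW": "cw",
       "CHI_TETRAHEDRAL_CCW": "ccw"}


def _load(rec):
    """Return a sanitized heavy-atom RDKit mol (coords kept if present)."""
    if rec.get("sdf") is not None:
        mol = Chem.MolFromMolBlock(rec["sdf"], sanitize=True, removeHs=True)
    else:
        mol = Chem.MolFromSmiles(rec["smiles"])
    if mol is None:
        raise ValueError("unparseable input")
    mol = Chem.RemoveHs(mol)
    if mol.GetNumHeavyAtoms() == 0:
        raise ValueError("zero heavy atoms")
    Chem.AssignStereochemistry(mol, cleanIt=True, force=True)
    return mol


def _describe(mol):
    atoms = []
    for a in mol.GetAtoms():
        atoms.append({
            "element": a.GetSymbol(),
            "formal_charge": a.GetFormalCharge(),
            "degree": a.GetDegree(),
            "num_h": a.GetTotalNumHs(),
            "hybridization": HYB.get(str(a.GetHybridization()), "other"),
            "aromatic": bool(a.GetIsAromatic()),
            "in_ring": bool(a.IsInRing()),
            "chirality": CHI.get(str(a.GetChiralTag()), "other"),
        })
    kek = Chem.Mol(mol)
    Chem.Kekulize(kek, clearAromaticFlags=True)
    bonds = []
    for b in mol.GetBonds():
        kb = kek.GetBondBetweenAtoms(b.GetBeginAtomIdx(), b.GetEndAtomIdx())
        bonds.append({
            "i": b.GetBeginAtomIdx(),
            "j": b.GetEndAtomIdx(),
            "order": b.GetBondTypeAsDouble(),
            "kek_order": int(kb.GetBondTypeAsDouble()),
            "aromatic": bool(b.GetIsAromatic()),
            "in_ring": bool(b.IsInRing()),
            "stereo": str(b.GetStereo()).replace("STEREO", "").lower(),
        })
    out = {"n_atoms": mol.GetNumAtoms(), "atoms": atoms, "bonds": bonds,
           "coords": None}
    if mol.GetNumConformers() > 0:
        conf = mol.GetConformer()
        out["coords"] = [[conf.GetAtomPosition(i).x,
                          conf.GetAtomPosition(i).y,
                          conf.GetAtomPosition(i).z]
                         for i in range(mol.GetNumAtoms())]
    return out


def _embed(mol, n_candidates, seed):
    """Embed n candidates with ETKDG, MMFF94-optimize, keep lowest energy."""
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    params.numThreads = 1
    cids = AllChem.EmbedMultipleConfs(molh, numConfs=int(n_candidates),
                                      params=params)
    if len(cids) == 0:
        # retry with random coordinates (small/rigid cases)
        params.useRandomCoords = True
        cids = AllChem.EmbedMultipleConfs(molh, numConfs=int(n_candidates),
                                          params=params)
    if len(cids) == 0:
        if mol.GetNumAtoms() == 1:
            conf = Chem.Conformer(molh.GetNumAtoms())
            molh.AddConformer(conf, assignId=True)
            cids = [0]
        else:
            raise ValueError("conformer embedding failed")
    energies = {}
    props = AllChem.MMFFGetMoleculeProperties(molh)
    for cid in cids:
        if props is not None:
            ff = AllChem.MMFFGetMoleculeForceField(molh, props, confId=cid)
            if ff is not None:
                ff.Minimize(maxIts=500)
                energies[cid] = ff.CalcEnergy()
                continue
        energies[cid] = 0.0  # no MMFF parameters: keep embedded geometry
    best = min(sorted(energies), key=lambda c: (energies[c], c))
    out = Chem.RemoveHs(molh)
    keep = out.GetConformer(best)
    coords = [[keep.GetAtomPosition(i).x, keep.GetAtomPosition(i).y,
               keep.GetAtomPosition(i).z] for i in range(out.GetNumAtoms())]
    return coords


def run(req):
    op = req["op"]
    results = []
    for rec in req["molecules"]:
        res = {"id": rec["id"], "error": None}
        try:
            mol = _load(rec)
            if op == "parse":
                res.update(_describe(mol))
            elif op == "conformer":
                res.update(_describe(mol))
                res["coords"] = _embed(mol, req.get("n_candidates", 1),
                                       req.get("seed", 0))
            elif op == "stereo":
                opts = StereoEnumerationOptions(onlyUnassigned=False,
                                                unique=True)
                isomers = sorted(Chem.MolToSmiles(m)
                                 for m in EnumerateStereoisomers(mol, opts))
                res["n_stereocenters"] = len(
                    Chem.FindMolChiralCenters(mol, includeUnassigned=True,
                                              useLegacyImplementation=False))
                res["isomers"] = isomers
            elif op == "scaffold":
                core = MurckoScaffold.GetScaffoldForMol(mol)
                if req.get("generic", False):
                    core = MurckoScaffold.MakeScaffoldGeneric(core)
                res["scaffold"] = Chem.MolToSmiles(core)
            else:
                raise ValueError("unknown op %r" % op)
        except Exception as exc:  # reported per molecule, batch continues
            res["error"] = str(exc)
        results.append(res)
    return {"results": results}


if __name__ == "__main__":
    with open(sys.argv[1]) as fh:
        request = json.load(fh)
    response = run(request)
    with open(sys.argv[2], "w") as fh:
        json.dump(response, fh)
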