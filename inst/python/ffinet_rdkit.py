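"""RDKit subprocess bridge.

Called as: python ffinet_rdkit.py <command> <request.json> <response.json>

Commands
--------
molecules       parse SMILES, optionally embed an ETKDG conformer, featurize
read_structure  read one molecule from SDF / PDB / mol2 with coordinates
validate        cheap parseability check for a list of SMILES

All atom indices in the JSON exchanged with R are 1-based. Only heavy atoms
are reported; hydrogens are folded into the per-atom H-count feature.
"""

import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Lipinski

RDLogger.DisableLog("rdApp.*")

FEATURE_VERSION = "ffinet-features-1"

# one-hot vocabularies; every family closes with an implicit "other" bucket
ATOMIC_NUMS = [5, 6, 7, 8, 9, 14, 15, 16, 17, 35, 53]
FORMAL_CHARGES = [-2, -1, 0, 1, 2]
CHIRAL_TAGS = [
    Chem.ChiralType.CHI_UNSPECIFIED,
    Chem.ChiralType.CHI_TETRAHEDRAL_CW,
    Chem.ChiralType.CHI_TETRAHEDRAL_CCW,
]
NUM_HS = [0, 1, 2, 3, 4]
HYBRIDIZATIONS = [
    Chem.HybridizationType.SP,
    Chem.HybridizationType.SP2,
    Chem.HybridizationType.SP3,
    Chem.HybridizationType.SP3D,
    Chem.HybridizationType.SP3D2,
]

N_FEATURES = (len(ATOMIC_NUMS) + 1) + (len(FORMAL_CHARGES) + 1) + \
    (len(CHIRAL_TAGS) + 1) + (len(NUM_HS) + 1) + \
    (len(HYBRIDIZATIONS) + 1) + 1 + 1 + 2  # = 38


def one_hot(value, vocab):
    row = [0.0] * (len(vocab) + 1)
    try:
        row[vocab.index(value)] = 1.0
    except ValueError:
        row[-1] = 1.0
    return row


def featurize(mol):
    donors = {i for match in mol.GetSubstructMatches(Lipinski.HDonorSmarts)
              for i in match}
    acceptors = {i for match in mol.GetSubstructMatches(Lipinski.HAcceptorSmarts)
                 for i in match}
    rows = []
    for atom in mol.GetAtoms():
        row = []
        row += one_hot(atom.GetAtomicNum(), ATOMIC_NUMS)
        row += one_hot(atom.GetFormalCharge(), FORMAL_CHARGES)
        row += one_hot(atom.GetChiralTag(), CHIRAL_TAGS)
        row += one_hot(atom.GetTotalNumHs(), NUM_HS)
        row += one_hot(atom.GetHybridization(), HYBRIDIZATIONS)
        row.append(1.0 if atom.GetIsAromatic() else 0.0)
        row.append(atom.GetMass() / 100.0)
        row.append(1.0 if atom.GetIdx() in donors else 0.0)
        row.append(1.0 if atom.GetIdx() in acceptors else 0.0)
        rows.append(row)
    return rows


def bond_table(mol):
    """[[i, j, order]] with 1-based indices; kekulized integer orders where
    possible, order 4 for aromatic bonds that resist kekulization."""
    orders = {}
    kek = Chem.Mol(mol)
    try:
        Chem.Kekulize(kek, clearAromaticFlags=True)
        for b in kek.GetBonds():
            orders[(b.GetBeginAtomIdx(), b.GetEndAtomIdx())] = \
                int(b.GetBondTypeAsDouble())
    except Exception:
        pass
    out = []
    for b in mol.GetBonds():
        i, j = b.GetBeginAtomIdx(), b.GetEndAtomIdx()
        order = orders.get((i, j))
        if order is None:
            order = 4 if b.GetIsAromatic() else max(1, int(b.GetBondTypeAsDouble()))
        out.append([i + 1, j + 1, order])
    return out


def record_from_mol(mol, with_positions=True):
    if mol.GetNumAtoms() == 0:
        raise ValueError("empty structure (zero heavy atoms)")
    rec = {
        "n_atoms": mol.GetNumAtoms(),
        "symbols": [a.GetSymbol() for a in mol.GetAtoms()],
        "features": featurize(mol),
        "bonds": bond_table(mol),
        "feature_version": FEATURE_VERSION,
    }
    if with_positions:
        conf = mol.GetConformer()
        rec["positions"] = [[conf.GetAtomPosition(i).x,
                             conf.GetAtomPosition(i).y,
                             conf.GetAtomPosition(i).z]
                            for i in range(mol.GetNumAtoms())]
    return rec


def embed_smiles(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        raise ValueError("unparseable SMILES: %r" % smiles)
    molh = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = int(seed)
    fallback = False
    if AllChem.EmbedMolecule(molh, params) < 0:
        params = AllChem.ETKDGv3()
        params.randomSeed = int(seed)
        params.useRandomCoords = True
        fallback = True
        if AllChem.EmbedMolecule(molh, params) < 0:
            raise ValueError("conformer embedding failed: %r" % smiles)
    heavy = Chem.RemoveHs(molh)
    rec = record_from_mol(heavy, with_positions=True)
    rec["used_random_coords"] = fallback
    rec["canonical_smiles"] = Chem.MolToSmiles(mol)
    return rec


def cmd_molecules(req):
    results = []
    for item in req["items"]:
        try:
            if item.get("embed", True):
                rec = embed_smiles(item["smiles"], item.get("seed", 0))
            else:
                mol = Chem.MolFromSmiles(item["smiles"])
                if mol is None:
                    raise ValueError("unparseable SMILES: %r" % item["smiles"])
                rec = record_from_mol(mol, with_positions=False)
                rec["canonical_smiles"] = Chem.MolToSmiles(mol)
            rec["ok"] = True
            results.append(rec)
        except Exception as exc:  # reported back to R as a per-item failure
            results.append({"ok": False, "error": str(exc)})
    return {"results": results}


def cmd_validate(req):
    return {"ok": [Chem.MolFromSmiles(s) is not None for s in req["smiles"]]}


def read_structure(path, fmt):
    if fmt == "sdf":
        supplier = Chem.SDMolSupplier(path, removeHs=True, sanitize=True)
        mol = next(iter(supplier), None)
        if mol is None:  # retry without sanitization
            supplier = Chem.SDMolSupplier(path, removeHs=True, sanitize=False)
            mol = next(iter(supplier), None)
    elif fmt == "mol2":
        mol = Chem.MolFromMol2File(path, removeHs=True)
        if mol is None:
            mol = Chem.MolFromMol2File(path, removeHs=True, sanitize=False)
    elif fmt == "pdb":
        mol = Chem.MolFromPDBFile(path, removeHs=True, proximityBonding=True)
        if mol is None:
            mol = Chem.MolFromPDBFile(path, removeHs=True, sanitize=False,
                                      proximityBonding=True)
    else:
        raise ValueError("unknown format: %r" % fmt)
    if mol is None:
        raise ValueError("could not read %s file: %s" % (fmt, path))
    try:
        mol.UpdatePropertyCache(strict=False)
        Chem.SetAromaticity(mol)
    except Exception:
        pass
    return record_from_mol(mol, with_positions=True)


def cmd_read_structure(req):
    rec = read_structure(req["path"], req["format"])
    rec["ok"] = True
    if req["format"] == "pdb":
        with open(req["path"]) as fh:
            rec["had_conect"] = any(line.startswith("CONECT") for line in fh)
    return rec


COMMANDS = {
    "molecules": cmd_molecules,
    "validate": cmd_validate,
    "read_structure": cmd_read_structure,
}


def main():
    command, infile, outfile = sys.argv[1], sys.argv[2], sys.argv[3]
    with open(infile) as fh:
        req = json.load(fh)
    try:
        resp = COMMANDS[command](req)
        resp["bridge_ok"] = True
    except Exception as exc:
        resp = {"bridge_ok": False, "error": str(exc)}
    with open(outfile, "w") as fh:
        json.dump(resp, fh)


if __name__ == "__main__":
    main()
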