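"""Helper for conformer embedding and substructure queries via RDKit.

Called by the R package as a one-shot subprocess; all I/O is JSON on
stdout. Atom indexing is RDKit order for MolFromSmiles + AddHs, so heavy
atom indices are stable between `embed` and `match` for the same SMILES.

Commands:
  embed <smiles> <seed>   3D conformer (ETKDG, seeded, deterministic),
                          Gasteiger charges, Crippen logP contributions,
                          donor/acceptor flags, ring membership.
  match <smiles> <smarts> substructure matches as 1-based index tuples.
"""
import json
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Lipinski, rdMolDescriptors

RDLogger.DisableLog("rdApp.*")


def die(msg):
    json.dump({"error": msg}, sys.stdout)
    sys.exit(0)


def embed(smiles, seed):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        die("unparsable SMILES: " + smiles)
    mol = Chem.AddHs(mol)
    params = AllChem.ETKDGv3()
    params.randomSeed = seed
    if AllChem.EmbedMolecule(mol, params) != 0:
        die("embedding failed for: " + smiles)
    AllChem.MMFFOptimizeMolecule(mol, maxIters=2000)
    AllChem.ComputeGasteigerCharges(mol)
    crippen = rdMolDescriptors._CalcCrippenContribs(mol)
    donors = {i for match in mol.GetSubstructMatches(Lipinski.HDonorSmarts)
              for i in match}
    acceptors = {i for match in mol.GetSubstructMatches(Lipinski.HAcceptorSmarts)
                 for i in match}
    conf = mol.GetConformer()
    atoms = []
    for atom in mol.GetAtoms():
        i = atom.GetIdx()
        pos = conf.GetAtomPosition(i)
        atoms.append({
            "element": atom.GetSymbol(),
            "charge": round(float(atom.GetDoubleProp("_GasteigerCharge")), 6),
            "x": round(pos.x, 6), "y": round(pos.y, 6), "z": round(pos.z, 6),
            "logp": round(crippen[i][0], 6),
            "donor": i in donors,
            "acceptor": i in acceptors,
            "formal": atom.GetFormalCharge(),
            "aromatic": atom.GetIsAromatic(),
        })
    rings = [[i + 1 for i in ring] for ring in mol.GetRingInfo().AtomRings()]
    bonds = [[b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1,
              int(b.GetBondTypeAsDouble()) or 1]
             for b in mol.GetBonds()]
    json.dump({"smiles": smiles, "seed": seed, "atoms": atoms, "rings": rings,
               "bonds": bonds}, sys.stdout)


def match(smiles, smarts):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        die("unparsable SMILES: " + smiles)
    mol = Chem.AddHs(mol)
    query = Chem.MolFromSmarts(smarts)
    if query is None:
        die("unparsable SMARTS: " + smarts)
    hits = mol.GetSubstructMatches(query, uniquify=True, maxMatches=200)
    json.dump({"matches": [[i + 1 for i in hit] for hit in hits]}, sys.stdout)


def main():
    if len(sys.argv) < 4:
        die("usage: rdkit_helper.py embed|match <smiles> <seed|smarts>")
    cmd = sys.argv[1]
    if cmd == "embed":
        embed(sys.argv[2], int(sys.argv[3]))
    elif cmd == "match":
        match(sys.argv[2], sys.argv[3])
    else:
        die("unknown command: " + cmd)


if __name__ == "__main__":
    main()
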