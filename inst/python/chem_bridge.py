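"""Batch chemistry helper for the asbscaffold R package.

All structure-level primitives are delegated to RDKit through this script:
canonicalization (with salt stripping), single-cut fragmentation at
configurable retrosynthetic bond patterns, fragment reassembly, and SDF
reading.  The R side always calls it in batch mode (one process per table)
to amortize interpreter start-up.

Modes (TSV in, TSV out, tab-separated, with header):
  canon    in: id, smiles            out: id, canonical, heavy_atoms,
                                          n_stripped, error
  frag     in: id, smiles  (+--rules) out: parent_id, rule_id, core,
                                          core_ha, sub, sub_ha
  join     in: id, core, sub         out: id, smiles, error
  sdf2smi  in: SDF (V2000) file      out: id, smiles

Attachment points are written as the bare wildcard atom (`*`) in RDKit
canonical SMILES; `[*]` on input is equivalent.
"""

import argparse
import csv
import sys

from rdkit import Chem, RDLogger

RDLogger.DisableLog("rdApp.*")


def heavy_atoms(mol):
    """Non-hydrogen, non-wildcard atom count."""
    return sum(1 for a in mol.GetAtoms() if a.GetAtomicNum() > 1)


def read_tsv(path):
    with open(path, newline="") as fh:
        return list(csv.DictReader(fh, delimiter="\t"))


def write_tsv(path, header, rows):
    with open(path, "w", newline="") as fh:
        w = csv.writer(fh, delimiter="\t", lineterminator="\n")
        w.writerow(header)
        w.writerows(rows)


def canon_one(smi):
    """Canonicalize one SMILES; strip to largest covalent component.

    Returns (canonical, heavy_atoms, n_stripped, error).
    """
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return ("", 0, 0, "parse_failure")
    frags = Chem.GetMolFrags(mol, asMols=True, sanitizeFrags=False)
    n_stripped = 0
    if len(frags) > 1:
        frags = sorted(frags, key=heavy_atoms, reverse=True)
        mol = frags[0]
        n_stripped = len(frags) - 1
    if heavy_atoms(mol) < 1:
        return ("", 0, n_stripped, "no_heavy_atoms")
    return (Chem.MolToSmiles(mol), heavy_atoms(mol), n_stripped, "")


def mode_canon(args):
    rows = []
    for rec in read_tsv(args.infile):
        canonical, ha, nstr, err = canon_one(rec["smiles"])
        rows.append([rec["id"], canonical, ha, nstr, err])
    write_tsv(args.outfile, ["id", "canonical", "heavy_atoms", "n_stripped", "error"], rows)


def load_rules(path):
    """Bond-cut rules: TSV with rule_id, smarts.  File order = priority.

    Each SMARTS must carry atom maps :1 and :2 on the two atoms of the
    bond to cut; additional unmapped atoms act as context constraints.
    """
    rules = []
    for rec in read_tsv(path):
        patt = Chem.MolFromSmarts(rec["smarts"])
        if patt is None:
            sys.exit("bad SMARTS for rule %s: %s" % (rec["rule_id"], rec["smarts"]))
        amap = {}
        for i, a in enumerate(patt.GetAtoms()):
            if a.GetAtomMapNum() in (1, 2):
                amap[a.GetAtomMapNum()] = i
        if sorted(amap) != [1, 2]:
            sys.exit("rule %s must map exactly atoms :1 and :2" % rec["rule_id"])
        rules.append((rec["rule_id"], patt, amap))
    return rules


def cut_bonds(mol, rules):
    """Map bond index -> rule_id of the first (highest-priority) matching rule."""
    hit = {}
    for rule_id, patt, amap in rules:
        for match in mol.GetSubstructMatches(patt):
            bond = mol.GetBondBetweenAtoms(match[amap[1]], match[amap[2]])
            if bond is not None and not bond.IsInRing():
                hit.setdefault(bond.GetIdx(), rule_id)
    return hit


def frag_one(parent_id, smi, rules):
    """All single-cut fragment pairs of one molecule, both orientations.

    Duplicate (core, sub) pairs arising from molecular symmetry are
    collapsed, keeping the first rule in priority order.
    """
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        return []
    out = {}
    hits = cut_bonds(mol, rules)
    for bidx in sorted(hits):
        rule_id = hits[bidx]
        pieces = Chem.FragmentOnBonds(mol, [bidx], addDummies=True, dummyLabels=[(0, 0)])
        try:
            frags = Chem.GetMolFrags(pieces, asMols=True, sanitizeFrags=True)
        except Exception:
            continue
        if len(frags) != 2:  # ring bonds are excluded already; defensive
            continue
        smis = [Chem.MolToSmiles(f) for f in frags]
        has = [heavy_atoms(f) for f in frags]
        for i, j in ((0, 1), (1, 0)):
            out.setdefault((smis[i], smis[j]), [parent_id, rule_id, smis[i], has[i], smis[j], has[j]])
    return list(out.values())


def mode_frag(args):
    rules = load_rules(args.rules)
    rows = []
    for rec in read_tsv(args.infile):
        rows.extend(frag_one(rec["id"], rec["smiles"], rules))
    write_tsv(args.outfile, ["parent_id", "rule_id", "core", "core_ha", "sub", "sub_ha"], rows)


def join_one(core, sub):
    mc = Chem.MolFromSmiles(core)
    ms = Chem.MolFromSmiles(sub)
    if mc is None or ms is None:
        return ("", "parse_failure")
    for m in (mc, ms):
        ndum = 0
        for a in m.GetAtoms():
            if a.GetAtomicNum() == 0:
                a.SetAtomMapNum(1)
                ndum += 1
        if ndum != 1:
            return ("", "attachment_count")
    try:
        z = Chem.molzip(mc, ms)
        Chem.SanitizeMol(z)
    except Exception:
        return ("", "join_failure")
    return (Chem.MolToSmiles(z), "")


def mode_join(args):
    rows = []
    for rec in read_tsv(args.infile):
        smi, err = join_one(rec["core"], rec["sub"])
        rows.append([rec["id"], smi, err])
    write_tsv(args.outfile, ["id", "smiles", "error"], rows)


def mode_smi2sdf(args):
    w = Chem.SDWriter(args.outfile)
    w.SetKekulize(True)
    for rec in read_tsv(args.infile):
        mol = Chem.MolFromSmiles(rec["smiles"])
        if mol is None:
            continue
        mol.SetProp("_Name", rec["id"])
        w.write(mol)
    w.close()


def mode_sdf2smi(args):
    rows = []
    supp = Chem.SDMolSupplier(args.infile, sanitize=True)
    for i, mol in enumerate(supp):
        if mol is None:
            rows.append(["", "", "parse_failure"])
            continue
        name = mol.GetProp("_Name") if mol.HasProp("_Name") else "mol_%d" % (i + 1)
        rows.append([name, Chem.MolToSmiles(mol), ""])
    write_tsv(args.outfile, ["id", "smiles", "error"], rows)


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("mode", choices=["canon", "frag", "join",
                                     "sdf2smi", "smi2sdf"])
    ap.add_argument("--in", dest="infile", required=True)
    ap.add_argument("--out", dest="outfile", required=True)
    ap.add_argument("--rules")
    args = ap.parse_args()
    if args.mode == "frag" and not args.rules:
        sys.exit("frag mode requires --rules")
    {"canon": mode_canon, "frag": mode_frag, "join": mode_join,
     "sdf2smi": mode_sdf2smi, "smi2sdf": mode_smi2sdf}[args.mode](args)


if __name__ == "__main__":
    main()
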