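"""Batch evaluation of a pinned list of RDKit 2-D descriptors.

Reads a two-column TSV (id <TAB> SMILES) and writes a TSV with columns
id, ok, n_heavy and one column per descriptor name. Rows whose SMILES does
not parse get ok=0 and empty descriptor cells. Values are written with
repr() so the full double precision survives the round trip.
"""
import argparse
import csv
import sys


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--names", required=True, help="file with one descriptor name per line")
    ap.add_argument("--input", required=True, help="TSV: id <TAB> SMILES")
    ap.add_argument("--output", required=True, help="TSV result path")
    args = ap.parse_args()

    from rdkit import Chem, RDLogger
    from rdkit.Chem import Descriptors

    RDLogger.DisableLog("rdApp.*")

    with open(args.names) as fh:
        names = [line.strip() for line in fh if line.strip()]
    funcs = dict(Descriptors._descList)
    missing = [n for n in names if n not in funcs]
    if missing:
        sys.exit("unknown descriptor names: " + ", ".join(missing))

    with open(args.input) as fin, open(args.output, "w", newline="") as fout:
        out = csv.writer(fout, delimiter="\t", lineterminator="\n")
        out.writerow(["id", "ok", "n_heavy"] + names)
        for line in fin:
            line = line.rstrip("\n")
            if not line:
                continue
            ident, smi = line.split("\t", 1)
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.writerow([ident, 0, 0] + [""] * len(names))
                continue
            vals = []
            for n in names:
                try:
                    v = float(funcs[n](mol))
                except Exception:
                    v = float("nan")
                vals.append(repr(v))
            out.writerow([ident, 1, mol.GetNumHeavyAtoms()] + vals)


if __name__ == "__main__":
    main()
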