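"""Convert between the 10x HDF5 gene-barcode matrix and an MTX directory.

Usage:
  python h5_tool.py to-mtx  <in.h5>   <out_dir>
  python h5_tool.py from-mtx <mtx_dir> <out.h5>

Understands both CellRanger HDF5 layouts: the legacy one-group-per-genome
layout (group holds data/indices/indptr/shape plus genes, gene_names,
barcodes) and the v3 'matrix' group whose names live under matrix/features.
Arrays are CSC with shape (genes, cells).
"""
import sys
import os

import h5py
import numpy as np
import scipy.sparse as sp


def _decode(arr):
    return [x.decode() if isinstance(x, bytes) else str(x) for x in arr]


def load_h5(path):
    with h5py.File(path, "r") as f:
        groups = [k for k in f.keys() if isinstance(f[k], h5py.Group)]
        grp = None
        if "matrix" in f:
            grp = f["matrix"]
            feats = grp["features"]
            names = _decode(feats["name"][:])
        else:
            for g in groups:
                if "data" in f[g] and "indptr" in f[g]:
                    grp = f[g]
                    key = "gene_names" if "gene_names" in grp else "genes"
                    names = _decode(grp[key][:])
                    break
        if grp is None:
            sys.stderr.write(
                "unrecognized 10x HDF5 layout; top-level groups found: %s\n"
                % ", ".join(groups) if groups else "none")
            sys.exit(1)
        shape = tuple(int(x) for x in grp["shape"][:])
        mat = sp.csc_matrix(
            (grp["data"][:], grp["indices"][:], grp["indptr"][:]), shape=shape)
        barcodes = _decode(grp["barcodes"][:])
    return mat, names, barcodes


def write_mtx_dir(mat, names, barcodes, out_dir):
    os.makedirs(out_dir, exist_ok=True)
    coo = mat.tocoo()
    with open(os.path.join(out_dir, "matrix.mtx"), "w") as fh:
        fh.write("%%MatrixMarket matrix coordinate integer general\n")
        fh.write("%d %d %d\n" % (mat.shape[0], mat.shape[1], coo.nnz))
        for i, j, v in zip(coo.row, coo.col, coo.data):
            fh.write("%d %d %d\n" % (i + 1, j + 1, int(v)))
    with open(os.path.join(out_dir, "features.tsv"), "w") as fh:
        for k, name in enumerate(names):
            fh.write("ENSG%08d\t%s\tGene Expression\n" % (k + 1, name))
    with open(os.path.join(out_dir, "barcodes.tsv"), "w") as fh:
        fh.write("".join(b + "\n" for b in barcodes))


def read_mtx_dir(path):
    import scipy.io
    mat = scipy.io.mmread(os.path.join(path, "matrix.mtx")).tocsc()
    feat = os.path.join(path, "features.tsv")
    if not os.path.exists(feat):
        feat = os.path.join(path, "genes.tsv")
    names = [ln.split("\t")[1].rstrip("\n") for ln in open(feat)]
    barcodes = [ln.rstrip("\n") for ln in open(os.path.join(path, "barcodes.tsv"))]
    return mat, names, barcodes


def write_h5(mat, names, barcodes, path):
    mat = mat.tocsc()
    with h5py.File(path, "w") as f:
        g = f.create_group("matrix")
        g.create_dataset("data", data=mat.data.astype(np.int32))
        g.create_dataset("indices", data=mat.indices.astype(np.int64))
        g.create_dataset("indptr", data=mat.indptr.astype(np.int64))
        g.create_dataset("shape", data=np.array(mat.shape, dtype=np.int64))
        g.create_dataset("barcodes",
                         data=np.array([b.encode() for b in barcodes]))
        feats = g.create_group("features")
        feats.create_dataset(
            "id", data=np.array([("ENSG%08d" % (k + 1)).encode()
                                 for k in range(len(names))]))
        feats.create_dataset("name",
                             data=np.array([n.encode() for n in names]))
        feats.create_dataset(
            "feature_type",
            data=np.array([b"Gene Expression"] * len(names)))


def main(argv):
    if len(argv) != 4 or argv[1] not in ("to-mtx", "from-mtx"):
        sys.stderr.write(__doc__)
        sys.exit(2)
    if argv[1] == "to-mtx":
        mat, names, barcodes = load_h5(argv[2])
        write_mtx_dir(mat, names, barcodes, argv[3])
    else:
        mat, names, barcodes = read_mtx_dir(argv[2])
        write_h5(mat, names, barcodes, argv[3])


if __name__ == "__main__":
    main(sys.argv)
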