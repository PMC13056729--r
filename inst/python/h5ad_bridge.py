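"""Exchange bridge between .h5ad files and a plain-text mtx directory.

export: h5ad -> dir/{matrix.mtx, genes.tsv, barcodes.tsv, coordinates.csv}
import: dir (same layout, optionally embeddings.csv / domains.txt /
        imputed.csv) -> h5ad
"""
import sys

import numpy as np
import pandas as pd
import scipy.io as sio
import scipy.sparse as sp
import anndata as ad


def do_export(h5ad_path, out_dir):
    import os
    a = ad.read_h5ad(h5ad_path)
    if "spatial" not in a.obsm:
        sys.stderr.write("no spatial coordinates: obsm['spatial'] missing\n")
        sys.exit(2)
    X = a.X
    if sp.issparse(X):
        X = X.tocoo()
    else:
        X = sp.coo_matrix(np.asarray(X))
    sio.mmwrite(os.path.join(out_dir, "matrix.mtx"), X)
    with open(os.path.join(out_dir, "genes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, a.var_names)) + "\n")
    with open(os.path.join(out_dir, "barcodes.tsv"), "w") as fh:
        fh.write("\n".join(map(str, a.obs_names)) + "\n")
    co = pd.DataFrame({
        "spot_id": a.obs_names,
        "x": np.asarray(a.obsm["spatial"])[:, 0],
        "y": np.asarray(a.obsm["spatial"])[:, 1],
    })
    if "ground_truth" in a.obs:
        gt = a.obs["ground_truth"]
        co["ground_truth"] = pd.factorize(gt)[0] + 1 if gt.dtype == object or str(gt.dtype) == "category" else np.asarray(gt)
    co.to_csv(os.path.join(out_dir, "coordinates.csv"), index=False)


def do_import(in_dir, h5ad_path):
    import os
    X = sp.csr_matrix(sio.mmread(os.path.join(in_dir, "matrix.mtx")))
    genes = [l.strip() for l in open(os.path.join(in_dir, "genes.tsv")) if l.strip()]
    bars = [l.strip() for l in open(os.path.join(in_dir, "barcodes.tsv")) if l.strip()]
    co = pd.read_csv(os.path.join(in_dir, "coordinates.csv"))
    co = co.set_index("spot_id").loc[bars]
    a = ad.AnnData(X=X, obs=pd.DataFrame(index=bars), var=pd.DataFrame(index=genes))
    a.obsm["spatial"] = co[["x", "y"]].to_numpy(dtype=float)
    if "ground_truth" in co:
        a.obs["ground_truth"] = co["ground_truth"].to_numpy()
    emb = os.path.join(in_dir, "embeddings.csv")
    if os.path.exists(emb):
        a.obsm["X_spatialdg"] = pd.read_csv(emb).to_numpy(dtype=float)
    dom = os.path.join(in_dir, "domains.txt")
    if os.path.exists(dom):
        a.obs["spatialdg_domain"] = pd.Categorical(
            [l.strip() for l in open(dom) if l.strip() != ""])
    imp = os.path.join(in_dir, "imputed.csv")
    if os.path.exists(imp):
        a.layers["spatialdg_imputed"] = pd.read_csv(imp).to_numpy(dtype=float)
    a.write_h5ad(h5ad_path)


if __name__ == "__main__":
    if len(sys.argv) != 4 or sys.argv[1] not in {"export", "import"}:
        sys.stderr.write("usage: h5ad_bridge.py {export|import} <src> <dst>\n")
        sys.exit(1)
    if sys.argv[1] == "export":
        do_export(sys.argv[2], sys.argv[3])
    else:
        do_import(sys.argv[2], sys.argv[3])
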