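# Independent oracles used to cross-check the package's own numerics.

# Quaternion-method superposition RMSD (Horn 1987, closed form via the
# largest eigenvalue of the 4x4 key matrix). Shares no code with the
# SVD-based Kabsch implementation it checks.
quaternion_rmsd <- function(x, y) {
  X <- sweep(x, 2, colMeans(x))
  Y <- sweep(y, 2, colMeans(y))
  M <- t(X) %*% Y
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,        -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max((sum(X^2) + sum(Y^2) - 2 * lam) / nrow(x), 0))
}

# Total SASA from an independent reference implementation (biotite's
# Shrake-Rupley, via the system python); same element radii table.
biotite_total_sasa <- function(structure, probe = 1.4, n_points = 2000) {
  pdb_file <- tempfile(fileext = ".pdb")
  on.exit(unlink(pdb_file))
  write_pdb(structure, pdb_file)
  script <- sprintf('
import numpy as np
import biotite.structure as struc
import biotite.structure.io.pdb as pdbio
arr = pdbio.PDBFile.read("%s").get_structure(model=1)
s = struc.sasa(arr, probe_radius=%f, point_number=%d, vdw_radii="Single")
print(repr(float(np.nansum(s))))
', pdb_file, probe, n_points)
  out <- system2("python", "-", stdout = TRUE, input = script)
  as.numeric(out[length(out)])
}
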