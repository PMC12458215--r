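# Shrake-Rupley solvent-accessible surface area with atom-level
# charged/polar/apolar partitioning.

# Van der Waals radii (Angstrom) by element.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90)
VDW_DEFAULT <- 1.80

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
CHARGED_RESIDUES <- c("ASP", "GLU", "LYS", "ARG", "HIS")

#' Assign radii and polarity classes to atoms
#'
#' Radii come from a van-der-Waals table keyed by element. Polarity classes
#' partition every atom: `charged` = side-chain atoms of Asp/Glu/Lys/Arg/His;
#' `polar` = backbone N/O plus side-chain nitrogen/oxygen of the remaining
#' residues; `apolar` = all remaining atoms (carbons, sulfur, hydrogens).
#'
#' @param atoms data.frame from [read_pdb_atoms()] (element, name, resname).
#' @param radii named radius table overriding the default by element.
#' @return `atoms` with `radius` and `class` columns appended.
#' @export
assign_radii <- function(atoms, radii = VDW_RADII) {
  el <- toupper(atoms$element)
  r <- unname(radii[el])
  r[is.na(r)] <- VDW_DEFAULT
  if (any(r <= 0)) stop("all radii must be > 0")
  atoms$radius <- r
  side <- !toupper(atoms$name) %in% BACKBONE_ATOMS
  hetero <- el %in% c("N", "O")
  cls <- rep("apolar", nrow(atoms))
  cls[hetero] <- "polar"
  cls[side & toupper(atoms$resname) %in% CHARGED_RESIDUES] <- "charged"
  atoms$class <- cls
  atoms
}

# Deterministic near-uniform unit-sphere quadrature points (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic sphere-point quadrature: each atom's solvent-accessible sphere
#' (radius = vdW radius + probe) is sampled with `n_points` near-uniform
#' points, and the accessible fraction is the share of points not buried
#' inside any neighbouring atom's accessible sphere. Per-class totals
#' (charged / polar / apolar) partition the total SASA exactly, and the
#' fractions f_crg / f_plr / f_aplr are each class total divided by the
#' total.
#'
#' @param atoms data.frame with x, y, z, `radius` and `class` columns
#'   (see [assign_radii()]).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points quadrature points per atom (default 960; >= 100).
#' @return list: `per_atom` (numeric vector, Angstrom^2), `total`,
#'   `by_class` (sasa_crg, sasa_plr, sasa_aplr), `fractions`
#'   (f_crg, f_plr, f_aplr).
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  if (nrow(atoms) == 0L) stop("zero atoms")
  if (n_points < 100L) stop("n_points must be >= 100")
  need <- c("x", "y", "z", "radius")
  if (!all(need %in% names(atoms))) stop("atoms need columns x, y, z, radius (see assign_radii)")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atoms$radius + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  per_atom <- numeric(n)
  # exactly coincident identical atoms (e.g. altloc duplicates) would each
  # report a full sphere; keep the first and zero the rest
  dup <- duplicated(cbind(round(xyz, 9L), round(rad, 9L)))
  for (i in which(!dup)) {
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & seq_len(n) != i & !dup)
    p <- sweep(pts * rad[i], 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dd <- (p[acc, 1L] - xyz[j, 1L])^2 + (p[acc, 2L] - xyz[j, 2L])^2 +
            (p[acc, 3L] - xyz[j, 3L])^2
      acc[acc] <- dd >= rad[j]^2
    }
    per_atom[i] <- mean(acc) * 4 * pi * rad[i]^2
  }
  cls <- atoms$class %||% rep("apolar", n)
  by_class <- c(sasa_crg = sum(per_atom[cls == "charged"]),
                sasa_plr = sum(per_atom[cls == "polar"]),
                sasa_aplr = sum(per_atom[cls == "apolar"]))
  total <- sum(per_atom)
  fr <- if (total > 0) by_class / total else by_class * NA_real_
  names(fr) <- c("f_crg", "f_plr", "f_aplr")
  list(per_atom = per_atom, total = total, by_class = by_class,
       fractions = fr, n_points = n_points, probe = probe)
}
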