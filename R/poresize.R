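#' Bondi van der Waals radii
#'
#' Radii (Angstroms) for the elements appearing in the organic-cation panel.
#'
#' @return Named numeric vector of radii.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80)
}

# standard single-bond lengths (Angstroms) between the element pairs used by
# the cation builder
.bond_lengths <- c("N-C" = 1.50, "P-C" = 1.80, "C-C" = 1.53, "C-O" = 1.42,
                   "C-H" = 1.09, "O-H" = 0.96, "N-H" = 1.03, "P-H" = 1.40)

bond_length <- function(a, b) {
  k <- paste(a, b, sep = "-"); k2 <- paste(b, a, sep = "-")
  if (k %in% names(.bond_lengths)) return(.bond_lengths[[k]])
  if (k2 %in% names(.bond_lengths)) return(.bond_lengths[[k2]])
  stop(sprintf("no bond length for %s-%s", a, b))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension-reference-frame placement: position atom D bonded to C
# with bond length l, angle theta at C (A-B-C-D chain) and torsion tau.
nerf_place <- function(A, B, C, l, theta, tau) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- l * c(-cos(theta), sin(theta) * cos(tau), sin(theta) * sin(tau))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Specification of an organic cation for vertex-method sizing
#'
#' Describes a quaternary (or protonated) onium cation as a central atom plus
#' up to four substituent arms, each a linear chain of heavy elements (the
#' backbone of the substituent); `"H"` denotes a bare hydrogen substituent.
#' The 3-D structure is built deterministically in the fully extended
#' (all-anti) conformation with idealized bond lengths and tetrahedral
#' angles, matching the extended structures produced by 2-D chemical drawing
#' tools after energy minimization.
#'
#' @param name Cation label.
#' @param center Central atom element (`"N"` or `"P"`).
#' @param arms List of character vectors of heavy-atom elements along each
#'   substituent backbone (e.g. ethyl = `c("C", "C")`), or `"H"`.
#' @param charge Formal charge (metadata).
#' @return An object of class `cation_spec`.
#' @examples
#' cation_spec("TEA4", "N",
#'             list(c("C", "C"), c("C", "C"), c("C", "C"), c("C", "C")))
#' @export
cation_spec <- function(name, center, arms, charge = 1) {
  stopifnot(center %in% c("N", "P"), length(arms) >= 1, length(arms) <= 4)
  arms <- lapply(arms, as.character)
  structure(list(name = name, center = center, arms = arms, charge = charge),
            class = "cation_spec")
}

#' Deterministic 3-D embedding of a cation specification
#'
#' Builds extended (all-anti) 3-D coordinates: substituent arms leave the
#' central atom along tetrahedral directions; each chain atom is placed with
#' idealized bond lengths, tetrahedral angles and 180-degree torsions
#' (reference substituent: the next arm, cyclically). A terminal hydrogen is
#' appended anti to each heavy arm; that distal tip atom is the arm's vertex.
#' Hydrogen substituents are vertices themselves, but are only used for
#' sizing when fewer than two heavy arms exist (mono-substituted ions),
#' mirroring how vertex distances are read off a space-filling model.
#'
#' The construction is exactly reproducible; `seed` is accepted for interface
#' stability and has no effect.
#'
#' @param spec A [cation_spec()].
#' @param seed Ignored (deterministic construction).
#' @return An object of class `cation_geometry`: list with `vertices` (n x 3
#'   matrix, Angstroms), `vertex_elements`, `vertex_is_heavy_arm`, `spec`.
#' @export
build_cation <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "cation_spec"))
  tet_angle <- acos(-1 / 3)
  tetra <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  origin <- c(0, 0, 0)
  n_arm <- length(spec$arms)
  firsts <- lapply(seq_len(n_arm), function(i) {
    tetra[i, ] * bond_length(spec$center, spec$arms[[i]][1])
  })
  verts <- matrix(NA_real_, n_arm, 3)
  elements <- character(n_arm)
  heavy <- logical(n_arm)
  for (i in seq_len(n_arm)) {
    arm <- spec$arms[[i]]
    heavy[i] <- arm[1] != "H"
    if (!heavy[i]) {
      verts[i, ] <- firsts[[i]]
      elements[i] <- "H"
      next
    }
    ref <- if (n_arm > 1) firsts[[(i %% n_arm) + 1]] else firsts[[i]] + c(0, 0, 1)
    A <- ref; B <- origin; C <- firsts[[i]]
    prev_el <- arm[1]
    for (el in c(arm[-1], "H")) {
      D <- nerf_place(A, B, C, bond_length(prev_el, el), tet_angle, pi)
      A <- B; B <- C; C <- D
      prev_el <- el
    }
    verts[i, ] <- C
    elements[i] <- "H"
  }
  structure(list(vertices = verts, vertex_elements = elements,
                 vertex_is_heavy_arm = heavy, spec = spec),
            class = "cation_geometry")
}

#' Vertex-method molecular diameter
#'
#' For every unordered pair of vertex atoms, the internuclear distance plus
#' both van der Waals radii is an across-the-molecule caliper distance; the
#' diameter is the mean over all pairs. A single-vertex (effectively
#' monatomic) species has diameter twice its van der Waals radius.
#'
#' @param geometry A `cation_geometry` from [build_cation()], or a
#'   [cation_spec()] (embedded on the fly).
#' @param radii Named van der Waals radii table (Angstroms).
#' @return Diameter in Angstroms.
#' @examples
#' cation_diameter(cation_panel_specs()[["TEA3"]])  # ~8 A
#' @export
cation_diameter <- function(geometry, radii = bondi_radii()) {
  if (inherits(geometry, "cation_spec")) geometry <- build_cation(geometry)
  stopifnot(inherits(geometry, "cation_geometry"))
  use <- if (sum(geometry$vertex_is_heavy_arm) >= 2) {
    which(geometry$vertex_is_heavy_arm)
  } else {
    seq_len(nrow(geometry$vertices))
  }
  el <- geometry$vertex_elements[use]
  missing <- setdiff(el, names(radii))
  if (length(missing)) {
    stop(sprintf("no van der Waals radius for element(s): %s",
                 paste(missing, collapse = ", ")))
  }
  if (length(use) == 1) return(2 * radii[[el]])
  xyz <- geometry$vertices[use, , drop = FALSE]
  pairs <- utils::combn(length(use), 2)
  mean(apply(pairs, 2, function(p) {
    sqrt(sum((xyz[p[1], ] - xyz[p[2], ])^2)) + radii[[el[p[1]]]] + radii[[el[p[2]]]]
  }))
}

#' The organic-cation test panel
#'
#' Connectivity specifications for the eleven cations used to probe the open
#' pore: methylamine (MEA), dimethylamine (DMA), trimethylamine (TMA3),
#' tetramethylammonium (TMA4), tetramethylphosphonium (TMP), triethylamine
#' (TEA3), tetraethylammonium (TEA4), tetrakis(hydroxymethyl)phosphonium
#' (THP), N-methyl-D-glucamine (NMDG), tetrapropylammonium (TPA) and
#' tetrabutylammonium (TBA). Amines are specified in their protonated
#' (cationic) form.
#'
#' @return Named list of [cation_spec()] objects.
#' @export
cation_panel_specs <- function() {
  me <- c("C"); et <- c("C", "C"); pr <- c("C", "C", "C")
  bu <- c("C", "C", "C", "C")
  list(
    MEA  = cation_spec("MEA", "N", list(me, "H", "H", "H")),
    DMA  = cation_spec("DMA", "N", list(me, me, "H", "H")),
    TMA3 = cation_spec("TMA3", "N", list(me, me, me, "H")),
    TMA4 = cation_spec("TMA4", "N", list(me, me, me, me)),
    TMP  = cation_spec("TMP", "P", list(me, me, me, me)),
    TEA3 = cation_spec("TEA3", "N", list(et, et, et, "H")),
    TEA4 = cation_spec("TEA4", "N", list(et, et, et, et)),
    THP  = cation_spec("THP", "P", list(c("C", "O"), c("C", "O"),
                                        c("C", "O"), c("C", "O"))),
    NMDG = cation_spec("NMDG", "N",
                       list(me, c("C", "C", "C", "C", "C", "O"), "H", "H")),
    TPA  = cation_spec("TPA", "N", list(pr, pr, pr, pr)),
    TBA  = cation_spec("TBA", "N", list(bu, bu, bu, bu))
  )
}

#' Relative-current measurements for the wild-type cation panel
#'
#' Synthetic stand-in for the relative inward currents at -80 mV
#' (test cation / Na+) of the wild-type pore-sizing experiment, which exist
#' only graphically in the source data. Magnitudes are representative; the
#' permeant/impermeant split they encode is the reported one (permeant: MEA,
#' DMA, TMA4, TMA3, TMP, TEA3, TEA4, THP; impermeant: NMDG, TPA, TBA).
#'
#' @return Data frame with columns `name`, `relative_current`, `blocker`.
#' @export
wt_panel_currents <- function() {
  data.frame(
    name = c("MEA", "DMA", "TMA3", "TMA4", "TMP", "TEA3", "TEA4", "THP",
             "NMDG", "TPA", "TBA"),
    relative_current = c(0.85, 0.70, 0.55, 0.45, 0.40, 0.15, 0.08, 0.06,
                         0.006, 0.004, 0.003),
    blocker = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                FALSE, TRUE, TRUE)
  )
}

#' Classify cations as permeant or impermeant
#'
#' A cation is permeant when its relative current at -80 mV (test / Na+)
#' exceeds `leak_threshold`. Cations flagged as blockers keep their flag in
#' the output: their relative current understates permeability, so the flag
#' qualifies the classification rather than changing it.
#'
#' @param rows Data frame with columns `name`, `relative_current`, and
#'   optionally `blocker`; must include a sodium reference unless
#'   `relative_current` is already normalized (values are ratios to Na+).
#' @param leak_threshold Relative current below which conduction is
#'   indistinguishable from leak.
#' @return Data frame of class `permeation_table` with an added
#'   `classification` column (`"permeant"` / `"impermeant"`).
#' @export
classify_permeation <- function(rows, leak_threshold = 0.02) {
  stopifnot(is.data.frame(rows),
            all(c("name", "relative_current") %in% names(rows)))
  if (any(rows$relative_current < 0)) {
    stop("relative currents must be non-negative")
  }
  if (!"blocker" %in% names(rows)) rows$blocker <- FALSE
  rows$classification <- ifelse(rows$relative_current > leak_threshold,
                                "permeant", "impermeant")
  structure(rows, leak_threshold = leak_threshold,
            class = c("permeation_table", "data.frame"))
}

#' Minimum pore diameter from a classified cation panel
#'
#' The largest vertex-method diameter among permeant cations is a lower
#' bound on the open-pore diameter; the smallest impermeant diameter brackets
#' it from above (classification noise permitting -- permeant blockers can
#' break the ordering, which is reported, not hidden).
#'
#' @param perm A `permeation_table` from [classify_permeation()].
#' @param diameters Named numeric vector of diameters (Angstroms) covering
#'   every cation in `perm`.
#' @return An object of class `cutoff_estimate`: list with `cutoff_A`,
#'   `largest_permeant`, `smallest_impermeant` (name + diameter, or NULL),
#'   `ordering_consistent`, and `interpretation = "lower bound"`.
#' @examples
#' pt <- classify_permeation(wt_panel_currents())
#' d <- vapply(cation_panel_specs(), cation_diameter, numeric(1))
#' names(d) <- names(cation_panel_specs())
#' estimate_cutoff(pt, d)
#' @export
estimate_cutoff <- function(perm, diameters) {
  stopifnot(inherits(perm, "permeation_table"))
  missing <- setdiff(perm$name, names(diameters))
  if (length(missing)) {
    stop(sprintf("no diameter for: %s", paste(missing, collapse = ", ")))
  }
  pn <- perm$name[perm$classification == "permeant"]
  if (!length(pn)) stop("no permeant cation in the panel")
  dp <- diameters[pn]
  largest <- names(dp)[which.max(dp)]
  inn <- perm$name[perm$classification == "impermeant"]
  smallest <- NULL
  if (length(inn)) {
    di <- diameters[inn]
    smallest <- list(name = names(di)[which.min(di)], diameter_A = min(di))
  }
  structure(list(cutoff_A = unname(max(dp)),
                 largest_permeant = list(name = largest,
                                         diameter_A = unname(max(dp))),
                 smallest_impermeant = smallest,
                 ordering_consistent = is.null(smallest) ||
                   max(dp) <= smallest$diameter_A,
                 interpretation = "lower bound"),
            class = "cutoff_estimate")
}

#' @export
print.cutoff_estimate <- function(x, ...) {
  cat(sprintf("minimum pore diameter (lower bound): %.2f A (largest permeant: %s)\n",
              x$cutoff_A, x$largest_permeant$name))
  if (!is.null(x$smallest_impermeant)) {
    cat(sprintf("  smallest impermeant: %s at %.2f A%s\n",
                x$smallest_impermeant$name, x$smallest_impermeant$diameter_A,
                if (x$ordering_consistent) "" else " (ordering inconsistent)"))
  }
  invisible(x)
}
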