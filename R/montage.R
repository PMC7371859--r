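#' Idealized 64-channel 10-10 sensor montage
#'
#' Returns the 3D positions of a standard 64-channel extended 10-20 ("10-10")
#' EEG cap on an idealized unit sphere (head-centered coordinates: +x right,
#' +y anterior, +z up, radius 1).  Positions are constructed geometrically:
#' the outermost electrode ring (Fp1/.../O1 etc.) sits 72 degrees from the
#' vertex, the 9/10 electrodes sit on the equator, and intermediate
#' electrodes are placed by spherical interpolation along the coronal arcs
#' between the outer ring and the midline.  The study hardware (64-channel
#' actiCAP) does not publish its exact geometry; this template is an
#' idealization adequate for neighbor graphs, interpolation weights and
#' topography definitions.
#'
#' @param n Number of channels: 64 (full cap) or 32 (reduced cap used for
#'   phantom recordings).
#' @return A data.frame with columns `label`, `x`, `y`, `z`.
#' @seealso [build_neighbors()]
#' @export
standard_montage <- function(n = 64) {
  if (!n %in% c(32L, 64L)) stop("standard_montage: n must be 32 or 64")
  deg <- pi / 180
  sph <- function(theta, phi) { # theta from vertex, phi from anterior midline, +phi = left
    c(x = -sin(theta * deg) * sin(phi * deg),
      y =  sin(theta * deg) * cos(phi * deg),
      z =  cos(theta * deg))
  }
  slerp <- function(a, b, f) {
    om <- acos(max(-1, min(1, sum(a * b))))
    if (om < 1e-12) return(a)
    (sin((1 - f) * om) * a + sin(f * om) * b) / sin(om)
  }
  pos <- list()
  # outer ring, 72 deg from vertex, azimuth steps of 18 deg (left hemisphere)
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
            TP7 = 108, P7 = 126, PO7 = 144, O1 = 162)
  for (lab in names(ring)) pos[[lab]] <- sph(72, ring[[lab]])
  # equatorial 9-electrodes
  for (lab in c(FT9 = 72, TP9 = 108, PO9 = 144)) NULL
  eq <- c(FT9 = 72, TP9 = 108, PO9 = 144)
  for (lab in names(eq)) pos[[lab]] <- sph(90, eq[[lab]])
  # midline (anterior-posterior fractions of the nasion-inion arc)
  mid <- c(Fz = 0.3, Cz = 0.5, CPz = 0.6, Pz = 0.7, POz = 0.8, Oz = 0.9)
  midpt <- function(p) sph(abs(0.5 - p) * 180, if (p <= 0.5) 0 else 180)
  for (lab in names(mid)) pos[[lab]] <- midpt(mid[[lab]])
  # virtual midline anchors for rows whose midline site is not in the cap
  anchors <- list(AFz = midpt(0.2), FCz = midpt(0.4))
  # coronal arcs: outer-ring electrode -> midline electrode
  arcs <- list(
    list(outer = "AF7", mid = anchors$AFz, labs = c(AF3 = 0.5)),
    list(outer = "F7",  mid = pos$Fz,  labs = c(F5 = 0.25, F3 = 0.5, F1 = 0.75)),
    list(outer = "FT7", mid = anchors$FCz, labs = c(FC5 = 0.25, FC3 = 0.5, FC1 = 0.75)),
    list(outer = "T7",  mid = pos$Cz,  labs = c(C5 = 0.25, C3 = 0.5, C1 = 0.75)),
    list(outer = "TP7", mid = pos$CPz, labs = c(CP5 = 0.25, CP3 = 0.5, CP1 = 0.75)),
    list(outer = "P7",  mid = pos$Pz,  labs = c(P5 = 0.25, P3 = 0.5, P1 = 0.75)),
    list(outer = "PO7", mid = pos$POz, labs = c(PO3 = 0.5)))
  for (a in arcs)
    for (lab in names(a$labs))
      pos[[lab]] <- slerp(pos[[a$outer]], a$mid, a$labs[[lab]])
  # mirror the left hemisphere to the right
  mirror <- c(Fp1 = "Fp2", AF7 = "AF8", AF3 = "AF4",
              F7 = "F8", F5 = "F6", F3 = "F4", F1 = "F2",
              FT9 = "FT10", FT7 = "FT8", FC5 = "FC6", FC3 = "FC4", FC1 = "FC2",
              T7 = "T8", C5 = "C6", C3 = "C4", C1 = "C2",
              TP9 = "TP10", TP7 = "TP8", CP5 = "CP6", CP3 = "CP4", CP1 = "CP2",
              P7 = "P8", P5 = "P6", P3 = "P4", P1 = "P2",
              PO9 = "PO10", PO7 = "PO8", PO3 = "PO4",
              O1 = "O2")
  for (lab in names(mirror)) {
    p <- pos[[lab]]
    pos[[mirror[[lab]]]] <- c(x = -p[["x"]], y = p[["y"]], z = p[["z"]])
  }
  order64 <- c("Fp1", "Fp2", "AF7", "AF3", "AF4", "AF8",
               "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
               "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
               "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
               "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
               "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
               "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
               "O1", "Oz", "O2")
  order32 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
               "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
               "P7", "P3", "Pz", "P4", "P8", "PO9", "O1", "Oz", "O2", "PO10")
  labs <- if (n == 64L) order64 else order32
  m <- t(vapply(labs, function(l) pos[[l]], numeric(3)))
  data.frame(label = labs, x = unname(m[, 1]), y = unname(m[, 2]),
             z = unname(m[, 3]), stringsAsFactors = FALSE)
}

#' Default neighbor distance for the shipped montage
#'
#' Euclidean (chord) distance on the unit-sphere template below which two
#' sensors are considered neighbors.  Chosen from the template geometry so
#' that every channel has between 3 and 8 neighbors (adjacent grid steps are
#' 0.31-0.40 chord units, diagonals about 0.5).
#' @export
default_neighbor_dist <- function() 0.45

#' Build a sensor neighbor graph from 3D positions
#'
#' Two channels are adjacent iff their Euclidean distance is `<= max_dist`.
#' The relation is symmetric and irreflexive.  Used for neighbor-weighted
#' channel interpolation, the low-correlation channel rejection rule, and
#' spatial clustering in the permutation test.
#'
#' @param positions Numeric matrix (channels x 3) or a data.frame with
#'   columns `x`, `y`, `z` (e.g. from [standard_montage()]); row order
#'   defines channel order.  Labels are taken from `label`/rownames if
#'   available.
#' @param max_dist Neighbor distance threshold; default
#'   [default_neighbor_dist()].
#' @return An object of class `NeighborGraph`: list with `adjacency`
#'   (logical channels x channels matrix) and `labels`.
#' @export
build_neighbors <- function(positions, max_dist = default_neighbor_dist()) {
  labels <- NULL
  if (is.data.frame(positions)) {
    if (!is.null(positions$label)) labels <- as.character(positions$label)
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  if (is.null(labels)) labels <- rownames(positions)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(positions)))
  if (nrow(positions) < 2L) stop("build_neighbors: need at least 2 channels")
  d <- as.matrix(stats::dist(positions))
  if (any(d[upper.tri(d)] < 1e-12))
    stop("build_neighbors: duplicate sensor positions")
  adj <- d <= max_dist
  diag(adj) <- FALSE
  dimnames(adj) <- list(labels, labels)
  structure(list(adjacency = adj, labels = labels, max_dist = max_dist),
            class = "NeighborGraph")
}

#' @export
print.NeighborGraph <- function(x, ...) {
  deg <- rowSums(x$adjacency)
  cat(sprintf("NeighborGraph: %d channels, degree %d-%d (median %g), max_dist=%g\n",
              length(x$labels), min(deg), max(deg), stats::median(deg), x$max_dist))
  invisible(x)
}

#' Channel groups by montage row
#'
#' Label-based selectors for the standard montage rows: `posterior_labels`
#' returns the parietal/parieto-occipital/occipital rows (the default
#' electrode set for alpha peak picking and PLV summaries),
#' `frontal_labels` the frontopolar/anterior-frontal rows (virtual EOG,
#' blink topographies).
#'
#' @param labels Character vector of 10-10 channel labels.
#' @return The matching subset of `labels`.
#' @export
posterior_labels <- function(labels)
  labels[grepl("^(P|PO|O)[0-9z]", labels)]

#' @rdname posterior_labels
#' @export
frontal_labels <- function(labels)
  labels[grepl("^(Fp|AF)[0-9z]", labels)]

temporal_labels <- function(labels)
  labels[grepl("^(T|TP|FT)[0-9]+$", labels)]
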