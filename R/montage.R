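#' Standard 64-channel EEG montage
#'
#' Builds an approximate spherical layout for a 64-electrode extended 10-20
#' ("10-10") set. Electrodes are placed on a unit sphere via an azimuthal
#' layout: each row (Fp, AF, F, FC, C, CP, P, PO, O) has a fixed
#' anterior-posterior coordinate and electrodes spread laterally within the
#' row. Positions are adequate for spatial adjacency, occipital selection
#' and synthetic topographies; they are not digitized coordinates.
#'
#' @return A data.frame with columns `label`, `x`, `y`, `z` (unit sphere;
#'   `x` right, `y` anterior, `z` superior).
#' @export
#' @examples
#' m <- standard_montage()
#' subset(m, label %in% c("Oz", "Cz"))
standard_montage <- function() {
  rows <- list(
    Fp = list(ap = 0.80, labs = c("Fp1", "Fpz", "Fp2"),
              lat = c(-0.25, 0, 0.25)),
    AF = list(ap = 0.62, labs = c("AF7", "AF3", "AFz", "AF4", "AF8"),
              lat = c(-0.55, -0.25, 0, 0.25, 0.55)),
    F  = list(ap = 0.45,
              labs = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
              lat = seq(-0.8, 0.8, by = 0.2)),
    FC = list(ap = 0.22,
              labs = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4",
                       "FC6", "FT8"),
              lat = seq(-0.9, 0.9, length.out = 9)),
    C  = list(ap = 0.00,
              labs = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
              lat = seq(-1, 1, by = 0.25)),
    CP = list(ap = -0.22,
              labs = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4",
                       "CP6", "TP8"),
              lat = seq(-0.9, 0.9, length.out = 9)),
    P  = list(ap = -0.45,
              labs = c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6",
                       "P8", "P10"),
              lat = seq(-1, 1, by = 0.2)),
    PO = list(ap = -0.62, labs = c("PO7", "PO3", "POz", "PO4", "PO8"),
              lat = c(-0.55, -0.25, 0, 0.25, 0.55)),
    O  = list(ap = -0.80, labs = c("O1", "Oz", "O2"),
              lat = c(-0.25, 0, 0.25)),
    I  = list(ap = -1.00, labs = "Iz", lat = 0)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(label = r$labs, ap = r$ap, lat = r$lat,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  # disc radius, clipped to the unit disc, then lifted to the sphere;
  # 1 disc unit spans ~100 degrees of arc from the vertex
  rho <- pmin(sqrt(out$ap^2 + out$lat^2), 1)
  beta <- rho * (100 * pi / 180)
  az <- atan2(out$lat, out$ap)
  az[rho == 0] <- 0
  data.frame(label = out$label,
             x = sin(beta) * sin(az),
             y = sin(beta) * cos(az),
             z = cos(beta),
             stringsAsFactors = FALSE)
}

#' Default occipital electrode set
#'
#' Labels averaged into the virtual occipital channel unless overridden.
#' @export
OCCIPITAL_LABELS <- c("O1", "Oz", "O2", "PO3", "PO4", "PO7", "PO8", "POz")

#' Sensor adjacency from electrode positions
#'
#' Symmetric neighborhood structure used by the spatial cluster permutation
#' test. Either the union of k-nearest-neighbor relations (`"knn"`,
#' symmetrized) or all pairs closer than `max_dist` (`"distance"`).
#'
#' @param positions matrix or data.frame with one row per sensor and columns
#'   x, y, z (a `label` column is carried through to dimnames).
#' @param method `"knn"` or `"distance"`.
#' @param k number of nearest neighbors (knn method).
#' @param max_dist distance cutoff (distance method), same units as
#'   positions.
#' @return Logical n x n symmetric adjacency matrix, FALSE diagonal.
#' @export
sensor_adjacency <- function(positions, method = c("knn", "distance"),
                             k = 4, max_dist = NULL) {
  method <- match.arg(method)
  labs <- NULL
  if (is.data.frame(positions)) {
    if ("label" %in% names(positions)) labs <- positions$label
    positions <- as.matrix(positions[, c("x", "y", "z")])
  }
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 sensors for adjacency")
  d <- as.matrix(stats::dist(positions))
  adj <- matrix(FALSE, n, n)
  if (method == "knn") {
    k <- min(k, n - 1L)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1L)]
      adj[i, nb] <- TRUE
    }
    adj <- adj | t(adj)
  } else {
    if (is.null(max_dist)) {
      nn <- apply(d + diag(Inf, n), 1, min)
      max_dist <- 1.5 * stats::median(nn)
    }
    adj <- d <= max_dist
  }
  diag(adj) <- FALSE
  dimnames(adj) <- list(labs, labs)
  adj
}
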