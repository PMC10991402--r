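#' Template 62-channel EEG montage
#'
#' Builds an idealized 62-electrode montage following the extended 10-20
#' layout used by TMS-compatible caps (ground at FPz, nose reference;
#' neither carries signal, so neither appears as a data channel). Positions
#' are placed on a sphere of radius 95 mm centred on the head centre, in an
#' MNI-like frame: +x right, +y anterior, +z superior (mm).
#'
#' Rows run Fp through O in 18-degree anterior-posterior steps from the
#' vertex; numbered electrodes step laterally along each coronal arc (odd =
#' left, even = right). The parieto-occipital row includes PO1/PO2 in
#' addition to PO3/PO4-style sites, matching the cap this layout emulates.
#'
#' @param radius scalp sphere radius in mm.
#' @return data.frame with columns \code{name}, \code{x}, \code{y}, \code{z}.
#' @examples
#' mon <- standardMontage()
#' nrow(mon)  # 62
#' @export
standardMontage <- function(radius = 95) {
  rows <- list(
    Fp = list(ap = 72, lab = c("Fp1", "Fp2"), lat = c(-18, 18)),
    AF = list(ap = 54, lab = c("AF7", "AF3", "AFz", "AF4", "AF8"),
              lat = c(-54, -27, 0, 27, 54)),
    F  = list(ap = 36, lab = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
              lat = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    FC = list(ap = 18, lab = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
              lat = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    C  = list(ap = 0, lab = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
              lat = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    CP = list(ap = -18, lab = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
              lat = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    P  = list(ap = -36, lab = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
              lat = c(-72, -54, -36, -18, 0, 18, 36, 54, 72)),
    PO = list(ap = -54, lab = c("PO7", "PO3", "PO1", "POz", "PO2", "PO4", "PO8"),
              lat = c(-54, -30, -12, 0, 12, 30, 54)),
    O  = list(ap = -72, lab = c("O1", "Oz", "O2"), lat = c(-18, 0, 18))
  )
  name <- unlist(lapply(rows, `[[`, "lab"), use.names = FALSE)
  ap <- unlist(lapply(rows, function(r) rep(r$ap, length(r$lab))), use.names = FALSE)
  lat <- unlist(lapply(rows, `[[`, "lat"), use.names = FALSE)
  a <- ap * pi / 180
  l <- lat * pi / 180
  # unit direction: lateral rotation about the AP axis, then AP tilt
  x <- sin(l)
  y <- sin(a) * cos(l)
  z <- cos(a) * cos(l)
  data.frame(name = name, x = radius * x, y = radius * y, z = radius * z,
             stringsAsFactors = FALSE)
}

#' Reduced montage keeping the analysis channels
#'
#' Selects \code{n} channels from the 62-channel template such that the
#' fronto-central sites used for TEP/ERP cluster extraction (Fz, FCz, FC1,
#' C1, C3, AFz, F1, F2, FC2, Cz) are always present; the remainder is an
#' evenly spread subset of the full montage. Useful for desk-scale
#' simulations.
#'
#' @param n number of channels (10..62).
#' @return montage data.frame with \code{n} rows.
#' @export
montageSubset <- function(n = 62) {
  mon <- standardMontage()
  if (n >= nrow(mon)) return(mon)
  essential <- c("Fz", "FCz", "FC1", "C1", "C3", "AFz", "F1", "F2", "FC2",
                 "Cz")
  if (n < length(essential))
    stop("need at least ", length(essential), " channels")
  keep <- match(essential, mon$name)
  rest <- setdiff(seq_len(nrow(mon)), keep)
  extra <- rest[round(seq(1, length(rest), length.out = n - length(keep)))]
  mon[sort(c(keep, extra)), , drop = FALSE]
}

#' Channel neighbourhood structure from montage geometry
#'
#' Two channels are neighbours when their Euclidean distance on the montage
#' is at most \code{maxDist} mm. Used by the sensor cluster permutation test.
#'
#' @param channels montage data.frame (name, x, y, z).
#' @param maxDist neighbour distance threshold (mm); 50 mm links adjacent
#'   sites of the template montage without bridging across one.
#' @return list of integer vectors: neighbours of each channel (self excluded).
#' @export
channelNeighbours <- function(channels, maxDist = 50) {
  pos <- as.matrix(channels[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(pos))
  n <- nrow(pos)
  if (n < 2) stop("need at least two channels to define neighbours")
  nb <- lapply(seq_len(n), function(i) {
    j <- which(d[i, ] <= maxDist & seq_len(n) != i)
    as.integer(j)
  })
  names(nb) <- channels$name
  if (all(lengths(nb) == 0))
    stop("no neighbours at maxDist = ", maxDist, " mm; montage too sparse")
  nb
}
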