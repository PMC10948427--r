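## Kolaskar-Tongaonkar antigenicity: sliding-window average of a per-residue
## antigenic propensity scale, with segment calling over the profile.

#' Kolaskar-Tongaonkar antigenic propensity scale
#'
#' Per-residue antigenic propensity values from Kolaskar & Tongaonkar (1990,
#' FEBS Letters 276:172-174), the scale behind the IEDB Antibody Epitope
#' Prediction tool and EMBOSS `antigenic`. Values above 1 mark residues
#' over-represented in experimentally known epitopes.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kt_scale <- function() {
  c(A = 1.064, C = 1.412, D = 0.866, E = 0.851, F = 1.091,
    G = 0.874, H = 1.105, I = 1.152, K = 0.930, L = 1.250,
    M = 0.826, N = 0.776, P = 1.064, Q = 1.015, R = 0.873,
    S = 1.012, T = 0.909, V = 1.383, W = 0.893, Y = 1.161)
}

#' Per-residue antigenic propensity profile
#'
#' Assigns each residue the mean Kolaskar-Tongaonkar scale value over the
#' window centred on it. Residues within `(window - 1) / 2` of either end
#' have no full window and carry `NA`.
#'
#' @param sequence amino-acid string over the 20 standard one-letter codes.
#' @param window odd window width in residues (default 7, the method's
#'   published setting).
#' @return Numeric vector of length `nchar(sequence)`, `NA` at the flanks.
#' @export
antigenic_propensity <- function(sequence, window = 7L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) < window)
    stop("sequence (length ", length(chars),
         ") shorter than window (", window, ")")
  bad <- which(!chars %in% names(kt_scale()))
  if (length(bad) > 0L)
    stop("invalid amino-acid character '", chars[bad[1]],
         "' at position ", bad[1])
  vals <- unname(kt_scale()[chars])
  half <- (window - 1L) %/% 2L
  n <- length(vals)
  prof <- rep(NA_real_, n)
  cs <- cumsum(c(0, vals))
  centers <- seq.int(half + 1L, n - half)
  prof[centers] <- (cs[centers + half + 1L] - cs[centers - half]) / window
  prof
}

#' Predict antigenic segments from a propensity profile
#'
#' Reports maximal runs of residues whose propensity exceeds the threshold,
#' keeping runs of at least `min_length` residues. By default the threshold
#' is the mean of the defined profile values for the protein, the behaviour
#' of the IEDB tool; runs must be strictly above it.
#'
#' @param propensity numeric profile from [antigenic_propensity()].
#' @param threshold numeric cut-off; `NULL` (default) uses the mean of the
#'   defined values.
#' @param min_length minimum segment length in residues (default 6).
#' @return `data.table` with columns `start_local`, `end_local`, `length`,
#'   `mean_propensity`; zero rows when nothing passes.
#' @export
predict_antigenic_segments <- function(propensity, threshold = NULL,
                                       min_length = 6L) {
  stopifnot(is.numeric(propensity))
  if (is.null(threshold)) threshold <- mean(propensity, na.rm = TRUE)
  above <- !is.na(propensity) & propensity > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_length
  if (!any(keep))
    return(data.table(start_local = integer(), end_local = integer(),
                      length = integer(), mean_propensity = numeric()))
  data.table(
    start_local = as.integer(starts[keep]),
    end_local = as.integer(ends[keep]),
    length = as.integer(runs$lengths[keep]),
    mean_propensity = vapply(which(keep), function(i)
      mean(propensity[starts[i]:ends[i]]), numeric(1))
  )
}
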