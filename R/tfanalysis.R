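#' Extract formants from a transfer function
#'
#' Formants are the local maxima of the transfer-function magnitude. Peak
#' frequencies are refined by 3-point parabolic interpolation of the dB
#' curve (resonances are locally quadratic in dB); bandwidths are the
#' half-power (-3 dB) widths, with the crossings located by linear
#' interpolation of the dB curve around each peak. Peaks whose half-power
#' span is not bracketed inside the sweep, or whose -3 dB region merges
#' with a neighbouring peak, are flagged invalid.
#'
#' @param tf A [transfer_function()] sampled on a uniform grid with
#'   `df <= 5` Hz.
#' @param n_max Maximum number of formants to return (default 5, the
#'   perceptually dominant set).
#' @return A `formant_table`: data frame with columns `k`, `F_hz`, `BW_hz`,
#'   `level_db`, `valid`.
#' @export
find_formants <- function(tf, n_max = 5L) {
  stopifnot(inherits(tf, "transfer_function"))
  f <- tf$freqs
  if (length(f) >= 2L) {
    df <- diff(f)
    if (max(df) - min(df) > 1e-6 * mean(df))
      stop("transfer function must be sampled on a uniform frequency grid")
    if (mean(df) > 5 + 1e-9)
      warning("frequency resolution coarser than 5 Hz; ",
              "formant estimates may be inaccurate")
  }
  y <- tf$db
  ok <- is.finite(y)
  empty <- formant_table(data.frame(k = integer(), F_hz = numeric(),
                                    BW_hz = numeric(), level_db = numeric(),
                                    valid = logical()))
  if (sum(ok) < 3L) return(empty)
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                 y[2:(n - 1)] >= y[3:n], FALSE)
  is_peak[!ok] <- FALSE
  idx <- which(is_peak)
  if (length(idx) == 0L) return(empty)
  idx <- utils::head(idx, n_max)

  dfreq <- f[2L] - f[1L]
  half <- 10 * log10(2)           # half-power drop in dB
  out <- lapply(seq_along(idx), function(q) {
    i <- idx[q]
    ym <- y[i - 1L]; y0 <- y[i]; yp <- y[i + 1L]
    denom <- ym - 2 * y0 + yp
    delta <- if (is.finite(denom) && denom < 0) 0.5 * (ym - yp) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    F_pk <- f[i] + delta * dfreq
    L_pk <- y0 - 0.25 * (ym - yp) * delta
    thr <- L_pk - half
    # walk left/right to the -3 dB crossings
    lo <- i
    while (lo > 1L && is.finite(y[lo]) && y[lo] > thr) lo <- lo - 1L
    hi <- i
    while (hi < n && is.finite(y[hi]) && y[hi] > thr) hi <- hi + 1L
    valid <- is.finite(y[lo]) && is.finite(y[hi]) &&
      y[lo] <= thr && y[hi] <= thr
    if (valid) {
      f_lo <- f[lo] + (thr - y[lo]) / (y[lo + 1L] - y[lo]) * dfreq
      f_hi <- f[hi] - (thr - y[hi]) / (y[hi - 1L] - y[hi]) * dfreq
      bw <- f_hi - f_lo
    } else bw <- NA_real_
    data.frame(k = q, F_hz = F_pk, BW_hz = bw, level_db = L_pk,
               valid = valid)
  })
  res <- do.call(rbind, out)
  if (any(res$valid & !is.na(res$BW_hz) & res$BW_hz >= res$F_hz))
    warning("bandwidth exceeds formant frequency for at least one peak; ",
            "spectrum is not tract-like")
  formant_table(res)
}

#' Formant table constructor
#'
#' @param df Data frame with columns `k`, `F_hz`, `BW_hz`, `level_db`,
#'   `valid`; `F_hz` must be strictly increasing and `k` contiguous from 1.
#' @return The validated `formant_table`.
#' @export
formant_table <- function(df) {
  need <- c("k", "F_hz", "BW_hz", "level_db", "valid")
  stopifnot(is.data.frame(df), all(need %in% names(df)))
  df <- df[order(df$F_hz), need, drop = FALSE]
  df$k <- seq_len(nrow(df))
  if (nrow(df) > 1L && any(diff(df$F_hz) <= 0))
    stop("formant frequencies must be strictly increasing")
  rownames(df) <- NULL
  structure(df, class = c("formant_table", "data.frame"))
}

#' Match found formants to a reference table
#'
#' Greedy nearest-frequency matching: repeatedly pair the globally closest
#' (reference, found) formants whose distance is within the window, until
#' no admissible pair remains. Reference formants left unmatched, and
#' matchings that would invert the frequency order, are flagged invalid -
#' these are the parameter-grid "white islands" where the transfer
#' function's peak structure has changed too much to track.
#'
#' @param found,reference `formant_table`s (nonempty).
#' @param window Matching window as a fraction of the reference frequency
#'   (default 0.2) or an absolute width in Hz when `window_hz = TRUE`.
#' @param window_hz Interpret `window` as Hz instead of a fraction.
#' @return Data frame with one row per reference formant: `k_ref`,
#'   `k_found` (NA if unmatched), `F_found`, `BW_found`, `valid`.
#' @export
match_to_reference <- function(found, reference, window = 0.2,
                               window_hz = FALSE) {
  stopifnot(inherits(found, "formant_table"),
            inherits(reference, "formant_table"),
            nrow(found) > 0L, nrow(reference) > 0L)
  win <- if (window_hz) rep(window, nrow(reference))
         else window * reference$F_hz
  d <- abs(outer(reference$F_hz, found$F_hz, "-"))
  admissible <- d <= matrix(win, nrow(reference), nrow(found))
  match_idx <- rep(NA_integer_, nrow(reference))
  dd <- d
  dd[!admissible] <- Inf
  while (any(is.finite(dd))) {
    ij <- arrayInd(which.min(dd), dim(dd))
    match_idx[ij[1L]] <- ij[2L]
    dd[ij[1L], ] <- Inf
    dd[, ij[2L]] <- Inf
  }
  valid <- !is.na(match_idx)
  # order inversion check: matched found frequencies must increase with k_ref
  mf <- found$F_hz[match_idx]
  if (sum(valid) > 1L) {
    fv <- mf[valid]
    if (any(diff(fv) <= 0)) valid[valid][c(FALSE, diff(fv) <= 0)] <- FALSE
  }
  data.frame(k_ref = reference$k,
             k_found = match_idx,
             F_found = mf,
             BW_found = found$BW_hz[match_idx],
             valid = valid)
}

#' Write a formant table as CSV (`k,F_hz,BW_hz,level_db,valid`)
#' @param ft A `formant_table`.
#' @param path Output path.
#' @export
write_formant_table <- function(ft, path) {
  utils::write.csv(as.data.frame(ft), path, row.names = FALSE)
  invisible(path)
}

#' Read a measured formant-target table
#'
#' Reads tables typed like published formant measurements: columns
#' `vowel, mode, k, F_khz, BW_hz`, with formant frequencies in kHz
#' (converted to Hz on read) and bandwidths in Hz.
#'
#' @param path CSV path.
#' @return Data frame with columns `vowel`, `mode`, `k`, `F_hz`, `BW_hz`.
#' @export
read_formant_targets <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vowel", "mode", "k", "F_khz", "BW_hz")
  if (!all(need %in% names(d)))
    stop("formant target CSV must have columns: ",
         paste(need, collapse = ", "))
  data.frame(vowel = d$vowel, mode = d$mode, k = as.integer(d$k),
             F_hz = 1000 * d$F_khz, BW_hz = d$BW_hz)
}

#' Convert target rows to a `formant_table`
#'
#' @param targets Data frame with `k`, `F_hz`, `BW_hz` (e.g. one
#'   vowel/mode subset of [read_formant_targets()]).
#' @return A `formant_table` with `valid = TRUE`.
#' @export
targets_as_formant_table <- function(targets) {
  formant_table(data.frame(k = targets$k, F_hz = targets$F_hz,
                           BW_hz = targets$BW_hz, level_db = NA_real_,
                           valid = TRUE))
}
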