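# Unit-m/z spectrum vectors, similarity, training loss, and MSP text I/O.
#
# A spectrum is a length-996 nonnegative vector; index i holds the intensity
# at integer m/z 14 + i, covering m/z 15..1010. Spectra are normalized to
# base peak 1.0 internally (cosine similarity is scale-invariant, so this
# cannot change a ranking); MSP files are written at base peak 999 for
# compatibility with the NIST text ecosystem.

MZ_MIN <- 15L
MZ_MAX <- 1010L
SPECTRUM_LENGTH <- MZ_MAX - MZ_MIN + 1L  # 996

#' Integer m/z axis of the spectrum representation
#'
#' @return Integer vector `15:1010` (length 996), element i being the m/z
#'   value of spectrum bin i.
#' @export
spectrum_mz <- function() seq.int(MZ_MIN, MZ_MAX)

#' Construct a spectrum vector
#'
#' @param intensities Nonnegative numeric vector of length 996 (m/z 15-1010).
#' @param normalize Scale so the base peak equals 1.0 (default); an all-zero
#'   vector is left unchanged.
#' @return An `ei_spectrum` numeric vector.
#' @export
spectrum_vector <- function(intensities, normalize = TRUE) {
  if (length(intensities) != SPECTRUM_LENGTH) {
    stop("spectrum vector must have length ", SPECTRUM_LENGTH,
         " (m/z ", MZ_MIN, "-", MZ_MAX, "), got ", length(intensities),
         call. = FALSE)
  }
  x <- as.numeric(intensities)
  if (anyNA(x) || any(x < 0)) {
    stop("spectrum intensities must be nonnegative and finite", call. = FALSE)
  }
  if (normalize && max(x) > 0) x <- x / max(x)
  structure(x, class = "ei_spectrum")
}

#' @export
print.ei_spectrum <- function(x, ...) {
  nz <- which(x > 0)
  cat(sprintf("<ei_spectrum> %d peak(s)", length(nz)))
  if (length(nz)) {
    top <- nz[order(x[nz], decreasing = TRUE)]
    top <- head(top, 5L)
    cat("; top: ",
        paste(sprintf("%d:%.3g", top + MZ_MIN - 1L, unclass(x)[top]),
              collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# round half away from zero (base round() is round-half-even)
.round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Bin a peak list into a spectrum vector
#'
#' Each peak's m/z is rounded to the nearest integer (half away from zero)
#' and its intensity added to the corresponding bin; intensities landing in
#' the same bin accumulate. Peaks falling outside m/z 15-1010 after rounding
#' are dropped with a warning reporting the dropped intensity.
#'
#' @param peaks Two-column matrix or data frame (`mz`, `intensity`).
#' @param normalize Scale the result to base peak 1.0 (default).
#' @return An `ei_spectrum` vector.
#' @examples
#' peaks_to_vector(cbind(mz = c(50.2, 77), intensity = c(100, 30)))
#' @export
peaks_to_vector <- function(peaks, normalize = TRUE) {
  peaks <- as.matrix(as.data.frame(peaks))
  if (!nrow(peaks)) {
    return(spectrum_vector(numeric(SPECTRUM_LENGTH), normalize = FALSE))
  }
  stopifnot(ncol(peaks) >= 2)
  mz <- as.numeric(peaks[, 1])
  intensity <- as.numeric(peaks[, 2])
  if (anyNA(mz) || anyNA(intensity)) {
    stop("peak list contains missing values", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("peak intensities must be nonnegative", call. = FALSE)
  }
  bin <- .round_half_up(mz)
  keep <- bin >= MZ_MIN & bin <= MZ_MAX
  if (any(!keep)) {
    warning(sprintf(
      "dropped %d peak(s) outside m/z %d-%d (total intensity %.4g)",
      sum(!keep), MZ_MIN, MZ_MAX, sum(intensity[!keep])), call. = FALSE)
  }
  x <- numeric(SPECTRUM_LENGTH)
  if (any(keep)) {
    idx <- bin[keep] - MZ_MIN + 1L
    agg <- rowsum(intensity[keep], idx)
    x[as.integer(rownames(agg))] <- agg[, 1]
  }
  spectrum_vector(x, normalize = normalize)
}

.as_spectrum <- function(x) {
  if (inherits(x, "ei_spectrum")) unclass(x)
  else unclass(spectrum_vector(x, normalize = FALSE))
}

#' Cosine similarity between two spectra
#'
#' \deqn{\cos(A, P) = \frac{\sum_i A_i P_i}{\sqrt{\sum_i A_i^2 \sum_i P_i^2}}}
#' over bins m/z 15-1010. Scale-invariant: multiplying either spectrum by a
#' positive constant leaves the result unchanged. With nonnegative
#' intensities the value lies in [0, 1].
#'
#' @param A,P Spectrum vectors (length 996, nonnegative).
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(A, P) {
  a <- .as_spectrum(A)
  p <- .as_spectrum(P)
  na <- sum(a * a)
  np <- sum(p * p)
  if (na == 0 || np == 0) {
    stop("cosine similarity is undefined for an all-zero spectrum",
         call. = FALSE)
  }
  sum(a * p) / sqrt(na * np)
}

# -- training loss -----------------------------------------------------------

# Registry of per-bin weight profiles for the squared-error training loss
# L = sum_i w(m_i) (A_i - P_i)^2. "uniform" (w = 1) is the default;
# "sqrt_mz" up-weights high-mass fragments by w = sqrt(m_i).
.LOSS_WEIGHTS <- list(
  uniform = function() rep(1, SPECTRUM_LENGTH),
  sqrt_mz = function() sqrt(spectrum_mz())
)

loss_weights <- function(weighting = c("uniform", "sqrt_mz")) {
  weighting <- match.arg(weighting)
  .LOSS_WEIGHTS[[weighting]]()
}

#' Training loss between a reference and a predicted spectrum
#'
#' Weighted squared error over all bins,
#' \eqn{L = \sum_i w(m_i) (A_i - P_i)^2}, zero iff the spectra are equal
#' bin-wise. The weight profile is selectable: `"uniform"` (default,
#' \eqn{w = 1}) or `"sqrt_mz"` (\eqn{w = \sqrt{m_i}}).
#'
#' @param A Reference spectrum vector (length 996).
#' @param P Predicted spectrum vector (length 996).
#' @param weighting Weight profile name.
#' @return Nonnegative scalar loss.
#' @export
training_loss <- function(A, P, weighting = c("uniform", "sqrt_mz")) {
  a <- .as_spectrum(A)
  p <- .as_spectrum(P)
  w <- loss_weights(weighting)
  sum(w * (a - p)^2)
}

# -- MSP text I/O ------------------------------------------------------------

#' Read an MSP spectral library file
#'
#' NIST text dialect: each record starts with `Name:`, may carry `Formula:`
#' and `MW:` headers, then `Num Peaks: N` followed by N `mz intensity`
#' pairs (one or several per line, separated by whitespace and/or
#' semicolons); records are separated by blank lines.
#'
#' @param path File path.
#' @param normalize Normalize each spectrum to base peak 1.0 (default).
#' @return List of records, each a list with `name`, `formula` (or `NA`),
#'   `mw` (or `NA`) and `spectrum` (an `ei_spectrum`).
#' @export
read_msp <- function(path, normalize = TRUE) {
  lines <- readLines(path)
  records <- list()
  i <- 1L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!grepl("^Name[[:space:]]*:", lines[i], ignore.case = TRUE)) {
      stop("MSP format error at line ", i, ": expected 'Name:' header, got ",
           sQuote(lines[i]), call. = FALSE)
    }
    rec <- list(name = trimws(sub("^Name[[:space:]]*:", "", lines[i],
                                  ignore.case = TRUE)),
                formula = NA_character_, mw = NA_real_)
    i <- i + 1L
    n_peaks <- NA_integer_
    while (i <= n_lines && nzchar(trimws(lines[i]))) {
      ln <- lines[i]
      if (grepl("^Num[[:space:]]*Peaks[[:space:]]*:", ln, ignore.case = TRUE)) {
        n_peaks <- as.integer(trimws(sub("^Num[[:space:]]*Peaks[[:space:]]*:",
                                         "", ln, ignore.case = TRUE)))
        i <- i + 1L
        break
      } else if (grepl("^Formula[[:space:]]*:", ln, ignore.case = TRUE)) {
        rec$formula <- trimws(sub("^Formula[[:space:]]*:", "", ln,
                                  ignore.case = TRUE))
      } else if (grepl("^MW[[:space:]]*:", ln, ignore.case = TRUE)) {
        rec$mw <- as.numeric(trimws(sub("^MW[[:space:]]*:", "", ln,
                                        ignore.case = TRUE)))
      }
      # other headers (Comments:, CAS#: ...) are tolerated and ignored
      i <- i + 1L
    }
    if (is.na(n_peaks)) {
      stop("MSP format error near line ", i, ": record ", sQuote(rec$name),
           " has no 'Num Peaks:' header", call. = FALSE)
    }
    vals <- numeric(0)
    peak_start <- i
    while (i <= n_lines && nzchar(trimws(lines[i])) &&
           length(vals) < 2L * n_peaks) {
      tok <- strsplit(trimws(lines[i]), "[;,[:space:]]+")[[1]]
      tok <- tok[nzchar(tok)]
      v <- suppressWarnings(as.numeric(tok))
      if (anyNA(v)) {
        stop("MSP format error at line ", i, ": non-numeric peak data ",
             sQuote(lines[i]), call. = FALSE)
      }
      vals <- c(vals, v)
      i <- i + 1L
    }
    if (length(vals) != 2L * n_peaks) {
      stop("MSP format error at line ", peak_start, ": record ",
           sQuote(rec$name), " declares ", n_peaks, " peaks but provides ",
           floor(length(vals) / 2), call. = FALSE)
    }
    peaks <- matrix(vals, ncol = 2L, byrow = TRUE)
    rec$spectrum <- peaks_to_vector(peaks, normalize = normalize)
    records[[length(records) + 1L]] <- rec
  }
  records
}

#' Write spectra to an MSP file
#'
#' Intensities are scaled to base peak 999 (NIST text convention) and
#' written at full double precision, so write-then-read reproduces the
#' normalized spectra exactly.
#'
#' @param records List of records: each needs `name` and `spectrum`
#'   (an `ei_spectrum` or length-996 vector); `formula` and `mw` are
#'   written when present. [build_library()] output also works, see
#'   [export_msp()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    x <- .as_spectrum(rec$spectrum)
    if (max(x) > 0) x <- x / max(x) * 999
    nz <- which(x > 0)
    writeLines(paste0("Name: ", rec$name), con)
    if (!is.null(rec$formula) && !is.na(rec$formula)) {
      writeLines(paste0("Formula: ", rec$formula), con)
    }
    if (!is.null(rec$mw) && !is.na(rec$mw)) {
      writeLines(paste0("MW: ", format(rec$mw, digits = 15)), con)
    }
    writeLines(paste0("Num Peaks: ", length(nz)), con)
    writeLines(sprintf("%d %s", nz + MZ_MIN - 1L,
                       format(x[nz], digits = 15, scientific = FALSE,
                              trim = TRUE)), con)
    writeLines("", con)
  }
  invisible(path)
}
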