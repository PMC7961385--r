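## Frequency-domain features and branch-input assembly.

#' Power half-spectrum of a window
#'
#' Squared magnitude of the FFT for bins 0 .. N/2 - 1 (the non-redundant
#' half of the mirrored spectrum of a real signal). Phase is discarded; no
#' taper is applied (rectangular window). For a matrix input the transform is
#' applied row-wise.
#'
#' @param x numeric vector of even length N, or a matrix whose rows are
#'   windows of even length
#' @param normalize min-max normalize each half-spectrum to [0, 1] (so the
#'   frequency inputs live on the same scale as the temporal ones)
#' @return vector of length N/2, or matrix with N/2 columns
#' @export
fft_power_halfspectrum <- function(x, normalize = FALSE) {
  if (is.matrix(x)) {
    n <- ncol(x)
    if (n %% 2 != 0) stop("window length must be even")
    sp <- Mod(stats::mvfft(t(x)))^2
    half <- t(sp[seq_len(n / 2), , drop = FALSE])
    if (normalize) half <- t(apply(half, 1, normalize01))
    return(half)
  }
  n <- length(x)
  if (n %% 2 != 0) stop("window length must be even")
  p <- Mod(stats::fft(x))^2
  out <- p[seq_len(n / 2)]
  if (normalize) out <- normalize01(out)
  out
}

#' Assemble per-branch model inputs from a windowed dataset
#'
#' Selects the 6 signals of a single modality (or all 12 for fusion) and
#' produces one input matrix per network branch: the temporal windows, their
#' [0, 1]-normalized FFT power half-spectra, or both (which doubles the
#' number of branches).
#'
#' @param signals named list of n x L temporal window matrices containing at
#'   least the signals of the requested modality (e.g. `dataset$signals`)
#' @param modality `"contact"`, `"radar"`, or `"fusion"`
#' @param data_type `"temporal"`, `"frequency"`, or `"both"`
#' @return named list of branch input matrices (n x L temporal and/or
#'   n x L/2 frequency)
#' @export
assemble_inputs <- function(signals, modality = c("contact", "radar", "fusion"),
                            data_type = c("temporal", "frequency", "both")) {
  modality <- match.arg(modality)
  data_type <- match.arg(data_type)
  wanted <- modality_signals(modality)
  missing <- setdiff(wanted, names(signals))
  if (length(missing)) {
    stop("missing signal(s) for modality '", modality, "': ",
         paste(missing, collapse = ", "))
  }
  inputs <- list()
  if (data_type %in% c("temporal", "both")) {
    for (nm in wanted) inputs[[paste0(nm, "_t")]] <- signals[[nm]]
  }
  if (data_type %in% c("frequency", "both")) {
    for (nm in wanted) {
      inputs[[paste0(nm, "_f")]] <-
        fft_power_halfspectrum(signals[[nm]], normalize = TRUE)
    }
  }
  inputs
}
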