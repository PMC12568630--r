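#' Build a single kinetic trace
#'
#' A trace is one time series of an instrument signal (FP in mP, anisotropy,
#' in-cell intensity ratio, absorbance or 1-D image intensity) together with
#' its experimental annotations. Concentrations are molar.
#'
#' @param time Numeric vector of times (seconds), strictly increasing.
#' @param signal Numeric vector, same length as `time`.
#' @param trace_id Identifier string.
#' @param kind One of `"mP"`, `"anisotropy"`, `"ratio"`, `"absorbance"`,
#'   `"intensity"`.
#' @param protein_conc,substrate_conc,competitor_conc Nominal concentrations
#'   (M).
#' @param replicate Replicate index (integer, 1-based).
#' @param n_averaged Number of replicates already averaged into this trace.
#' @return A data frame of class `slk_trace` with columns `time`, `signal`
#'   and the annotations stored as attributes.
#' @examples
#' trace(0:10, 60 + 0:10, trace_id = "a", protein_conc = 1e-7,
#'       substrate_conc = 2e-8)
#' @export
trace <- function(time, signal, trace_id = "trace", kind = "mP",
                  protein_conc = 0, substrate_conc = 0,
                  competitor_conc = 0, replicate = 1L, n_averaged = 1L) {
  stopifnot(is.numeric(time), is.numeric(signal),
            length(time) == length(signal), length(time) >= 1L,
            all(is.finite(time)), all(is.finite(signal)))
  if (any(diff(time) <= 0))
    stop("trace time must be strictly increasing")
  kind <- match.arg(kind,
                    c("mP", "anisotropy", "ratio", "absorbance", "intensity"))
  conc <- c(protein_conc, substrate_conc, competitor_conc)
  stopifnot(is.numeric(conc), all(is.finite(conc)))
  if (any(conc < 0)) stop("concentrations must be >= 0")
  structure(data.frame(time = as.numeric(time), signal = as.numeric(signal)),
            class = c("slk_trace", "data.frame"),
            trace_id = as.character(trace_id), kind = kind,
            protein_conc = protein_conc, substrate_conc = substrate_conc,
            competitor_conc = competitor_conc,
            replicate = as.integer(replicate),
            n_averaged = as.integer(n_averaged))
}

.trace_annotations <- function(x) {
  list(trace_id = attr(x, "trace_id"), kind = attr(x, "kind"),
       protein_conc = attr(x, "protein_conc"),
       substrate_conc = attr(x, "substrate_conc"),
       competitor_conc = attr(x, "competitor_conc"),
       replicate = attr(x, "replicate"),
       n_averaged = attr(x, "n_averaged"))
}

#' @export
print.slk_trace <- function(x, ...) {
  a <- .trace_annotations(x)
  cat(sprintf(
    "<slk_trace '%s'> %d points, %s; [P]0 = %.4g M, [S]0 = %.4g M%s\n",
    a$trace_id, nrow(x), a$kind, a$protein_conc, a$substrate_conc,
    if (a$competitor_conc > 0)
      sprintf(", [I]0/[competitor] = %.4g M", a$competitor_conc) else ""))
  invisible(x)
}

#' Build a concentration-series collection of traces
#'
#' A trace set groups the traces of one global-fit experiment: a shared
#' substrate concentration measured at several protein concentrations,
#' usually including a zero-protein baseline trace of the free fluorophore.
#'
#' @param traces A list of [trace()] objects.
#' @param design Instrument design: `"platereader"`, `"stoppedflow"`,
#'   `"competition"` or `"incell"`.
#' @return A list of class `slk_traceset`.
#' @export
trace_set <- function(traces, design = c("platereader", "stoppedflow",
                                         "competition", "incell")) {
  design <- match.arg(design)
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "slk_trace")))
  structure(list(traces = traces, design = design), class = "slk_traceset")
}

#' @export
print.slk_traceset <- function(x, ...) {
  p <- protein_concs(x)
  cat(sprintf("<slk_traceset> %s design, %d traces, [P]0 levels: %s M\n",
              x$design, length(x$traces),
              paste(signif(sort(unique(p)), 3), collapse = ", ")))
  invisible(x)
}

#' @export
length.slk_traceset <- function(x) length(x$traces)

#' Per-trace annotation accessors
#'
#' @param set An `slk_traceset`.
#' @return Numeric vector of per-trace nominal protein concentrations (M).
#' @export
protein_concs <- function(set) {
  stopifnot(inherits(set, "slk_traceset"))
  vapply(set$traces, function(tr) attr(tr, "protein_conc"), numeric(1))
}

.subset_traces <- function(set, keep) {
  out <- set
  out$traces <- set$traces[keep]
  out
}

# distinct non-baseline protein levels, used by fit identifiability checks
.n_protein_levels <- function(set) {
  length(unique(protein_concs(set)[protein_concs(set) > 0]))
}
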