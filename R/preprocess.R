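# Trace conditioning mirroring the standard instrument workflow:
# replicate averaging, pretrigger removal / time zeroing, and baseline
# extraction from zero-protein traces. No resampling is ever done:
# replicates of a stopped-flow shot share the hardware time grid, so a
# grid mismatch is an error, not something to interpolate away.

#' Average technical replicates sharing a common time grid
#'
#' Pointwise mean of the signals of replicate traces. All traces must have
#' identical time grids (to within 1e-9 s) and identical annotations except
#' for the replicate index; the number of averaged replicates is recorded
#' in the result.
#'
#' @param traces List of [trace()] objects (or an `slk_traceset`, in which
#'   case every replicate group is averaged and a trace set is returned).
#' @return A single averaged [trace()] (or a trace set of them).
#' @export
average_replicates <- function(traces) {
  if (inherits(traces, "slk_traceset")) {
    key <- vapply(traces$traces, function(tr)
      paste(attr(tr, "protein_conc"), attr(tr, "substrate_conc"),
            attr(tr, "competitor_conc"), attr(tr, "kind")), character(1))
    out <- lapply(split(traces$traces, factor(key, unique(key))),
                  average_replicates)
    return(trace_set(unname(out), design = traces$design))
  }
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, logical(1), "slk_trace")))
  if (length(traces) == 1L) return(traces[[1L]])
  t0 <- traces[[1L]]$time
  for (tr in traces[-1L]) {
    if (length(tr$time) != length(t0) || any(abs(tr$time - t0) > 1e-9))
      stop("replicate time grids differ; refusing to resample")
    for (f in c("protein_conc", "substrate_conc", "competitor_conc", "kind"))
      if (!identical(attr(tr, f), attr(traces[[1L]], f)))
        stop("replicates differ in annotation '", f, "'")
  }
  sig <- rowMeans(vapply(traces, function(tr) tr$signal,
                         numeric(length(t0))))
  a <- .trace_annotations(traces[[1L]])
  trace(t0, sig, trace_id = a$trace_id, kind = a$kind,
        protein_conc = a$protein_conc, substrate_conc = a$substrate_conc,
        competitor_conc = a$competitor_conc, replicate = 1L,
        n_averaged = sum(vapply(traces, function(tr)
          attr(tr, "n_averaged"), integer(1))))
}

#' Remove pretrigger samples and re-zero time
#'
#' Drops all samples recorded before `trigger_time` (the mixing trigger of
#' a stopped-flow shot) and shifts the remaining times so the first
#' retained sample is at t = 0. Applying it twice with `trigger_time = 0`
#' is a no-op.
#'
#' @param tr A [trace()] (or an `slk_traceset`, processed trace by trace).
#' @param trigger_time Trigger time in the trace's original time base
#'   (seconds).
#' @return The trimmed, re-zeroed trace (or trace set).
#' @export
trim_and_zero <- function(tr, trigger_time = 0) {
  if (inherits(tr, "slk_traceset")) {
    out <- tr
    out$traces <- lapply(tr$traces, trim_and_zero, trigger_time)
    return(out)
  }
  stopifnot(inherits(tr, "slk_trace"), is.numeric(trigger_time),
            length(trigger_time) == 1L)
  keep <- tr$time >= trigger_time
  if (!any(keep)) stop("all samples are pretrigger; empty trace")
  a <- .trace_annotations(tr)
  trace(tr$time[keep] - tr$time[keep][1L], tr$signal[keep],
        trace_id = a$trace_id, kind = a$kind,
        protein_conc = a$protein_conc, substrate_conc = a$substrate_conc,
        competitor_conc = a$competitor_conc, replicate = a$replicate,
        n_averaged = a$n_averaged)
}

#' Extract the free-fluorophore baseline from zero-protein traces
#'
#' The baseline `r_free` is the time-mean signal of the zero-protein
#' trace(s) of the set: without protein the fluorophore stays free and its
#' signal is flat, so the mean is the natural estimator. The returned map
#' marks `r_free` as fixed for downstream fits.
#'
#' @param set An `slk_traceset` containing at least one zero-protein trace.
#' @param bound_species Passed to [observable_map()].
#' @param r_bound Provisional bound-state signal for the map (refined by
#'   the fit); defaults to the maximum signal seen in the set.
#' @return An [observable_map()] with `r_free` set and flagged fixed.
#' @export
extract_baseline <- function(set, bound_species = "PS", r_bound = NULL) {
  stopifnot(inherits(set, "slk_traceset"))
  zero <- protein_concs(set) == 0
  if (!any(zero))
    stop("no zero-protein trace in set; baseline cannot be extracted")
  r_free <- mean(unlist(lapply(set$traces[zero], function(tr) tr$signal)))
  if (is.null(r_bound))
    r_bound <- max(vapply(set$traces, function(tr) max(tr$signal),
                          numeric(1)))
  observable_map(r_free, max(r_bound, r_free), bound_species = bound_species,
                 r_free_fixed = TRUE)
}
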