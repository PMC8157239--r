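#' Filter trace: the machine-readable filtering funnel
#'
#' Records, for every pipeline stage, the input count, output count and the
#' identifiers of surviving variants. Stage monotonicity (output a subset of
#' input) is asserted when a stage is appended, so a violated funnel fails
#' fast rather than producing an inconsistent report.
#'
#' @return an empty `filter_trace`.
#' @export
filter_trace <- function() {
  structure(list(stages = data.frame(stage = character(0),
                                     n_in = integer(0), n_out = integer(0),
                                     stringsAsFactors = FALSE),
                 ids = list()),
            class = "filter_trace")
}

#' Append a stage to a filter trace
#'
#' @param trace a [filter_trace()].
#' @param stage stage name.
#' @param ids_in,ids_out character vectors of variant ids entering and
#'   surviving the stage; `ids_out` must be a subset of `ids_in`.
#' @return the extended trace.
#' @export
trace_stage <- function(trace, stage, ids_in, ids_out) {
  if (!all(ids_out %in% ids_in))
    fv_abort(paste("funnel violation at stage", stage,
                   "- output is not a subset of input"))
  trace$stages <- rbind(trace$stages,
                        data.frame(stage = stage, n_in = length(ids_in),
                                   n_out = length(ids_out),
                                   stringsAsFactors = FALSE))
  trace$ids[[stage]] <- ids_out
  trace
}

#' @export
print.filter_trace <- function(x, ...) {
  cat(render_funnel(x), sep = "\n")
  invisible(x)
}

#' Render a filter trace as a text funnel
#'
#' One line per stage with input and output counts and percent retained,
#' mirroring the filtering-funnel figure style of familial variant studies.
#'
#' @param trace a [filter_trace()].
#' @return character vector of lines (header first).
#' @export
render_funnel <- function(trace) {
  hdr <- sprintf("%-28s %8s %8s %9s", "stage", "in", "out", "retained")
  if (!nrow(trace$stages)) return(hdr)
  pct <- ifelse(trace$stages$n_in > 0,
                100 * trace$stages$n_out / trace$stages$n_in, 100)
  c(hdr, sprintf("%-28s %8d %8d %8.1f%%", trace$stages$stage,
                 trace$stages$n_in, trace$stages$n_out, pct))
}
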