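# Surface versus internal probe pools from acid-quench / NH4Cl epochs.

#' Surface and internal probe pools from a three-epoch trace
#'
#' Partitions probe fluorescence into plasma-membrane (surface) and
#' intracellular (internal) pools using acid-quench and NH4Cl epochs:
#' surface = rest - acid, internal = NH4Cl - rest, with fractions normalised
#' to their sum. Epoch means exclude a transition period after each solution
#' switch so perfusion mixing does not bias them. Fractions are invariant to
#' affine rescaling of the arbitrary fluorescence units.
#'
#' @param trace Trace tibble of one bouton.
#' @param epoch_annotations Tibble with columns `label` (containing `rest`,
#'   `acid` and `nh4`), `start_s`, `end_s`; each epoch at least 5 s.
#' @param transition_s Seconds discarded after each epoch start.
#' @return A one-row tibble: `f_rest`, `f_acid`, `f_nh4`, `surface`,
#'   `internal`, `surface_fraction`, `internal_fraction`, `flagged`
#'   (TRUE with fractions NA when a pool is negative).
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 30, 0.1), bouton_id = "b1",
#'                      intensity = rep(c(100, 40, 200), each = 101))
#' ep <- tibble::tibble(label = c("rest", "acid", "nh4"),
#'                      start_s = c(0, 10, 20), end_s = c(10, 20, 30))
#' surface_internal_ratio(tr, ep, transition_s = 2)
surface_internal_ratio <- function(trace, epoch_annotations, transition_s = 2) {
  check_trace_df(trace)
  ep <- epoch_annotations
  need <- c("label", "start_s", "end_s")
  if (!all(need %in% names(ep))) {
    abort("epoch_annotations needs columns label, start_s, end_s")
  }
  get_mean <- function(what) {
    row <- ep[grepl(what, ep$label, ignore.case = TRUE), ]
    if (nrow(row) != 1) abort(sprintf("need exactly one '%s' epoch", what))
    if (row$end_s - row$start_s < 5) {
      abort(sprintf("'%s' epoch must be at least 5 s", what))
    }
    idx <- trace$time_s >= row$start_s + transition_s & trace$time_s < row$end_s
    if (!any(idx)) abort(sprintf("no samples in '%s' epoch after transition", what))
    mean(trace$intensity[idx])
  }
  f_rest <- get_mean("rest")
  f_acid <- get_mean("acid")
  f_nh4 <- get_mean("nh4")
  surface <- f_rest - f_acid
  internal <- f_nh4 - f_rest
  flagged <- surface < 0 || internal < 0
  if (flagged) {
    warn("negative pool value (expected f_nh4 >= f_rest >= f_acid); fractions not computed")
    sf <- NA_real_
    int_f <- NA_real_
  } else {
    tot <- surface + internal
    sf <- surface / tot
    int_f <- internal / tot
  }
  tibble(
    f_rest = f_rest, f_acid = f_acid, f_nh4 = f_nh4,
    surface = surface, internal = internal,
    surface_fraction = sf, internal_fraction = int_f, flagged = flagged
  )
}
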