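#' Thresholds for patella-baja classification
#'
#' @param ap_low Cutoff below which the postoperative AP index counts as
#'   abnormally low.
#' @param jap_low Cutoff below which the postoperative jAP index counts as
#'   abnormally low.
#' @param jlh_elevated_mm Cutoff on the post-minus-pre JLH difference above
#'   which the joint line counts as elevated. Default 5 mm, the lower end of
#'   the 5-8 mm elevation band that clinical series associate with poor
#'   outcomes.
#' @return An object of class `baja_thresholds`.
#' @export
baja_thresholds <- function(ap_low, jap_low, jlh_elevated_mm = 5) {
  for (v in list(ap_low, jap_low, jlh_elevated_mm))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("all thresholds must be single finite numbers", call. = FALSE)
  if (jlh_elevated_mm <= 0)
    stop("'jlh_elevated_mm' must be positive", call. = FALSE)
  structure(list(ap_low = ap_low, jap_low = jap_low,
                 jlh_elevated_mm = jlh_elevated_mm),
            class = "baja_thresholds")
}

#' Resolve classification thresholds
#'
#' Two modes. `"absolute"` passes explicit cutoffs through unchanged.
#' `"zscore"` derives "abnormally low" as mean - 2 SD of a user-supplied
#' reference cohort per index; no published normal range exists for the
#' axis-based indices, so the reference population is the caller's choice
#' (and should be stated alongside any call labels).
#'
#' @param mode `"absolute"` or `"zscore"`.
#' @param reference For `"absolute"`: a list/vector with `ap_low`, `jap_low`
#'   and optionally `jlh_elevated_mm`. For `"zscore"`: either a data frame of
#'   reference measurements with columns `AP` and `jAP` (at least 10 rows),
#'   or a list `list(AP = c(mean =, sd =), jAP = c(mean =, sd =))`.
#' @param jlh_elevated_mm JLH elevation cutoff in mm (default 5).
#' @param n_sd Number of reference SDs defining "low" in z-score mode
#'   (default 2).
#' @return A [baja_thresholds()] object.
#' @export
#' @examples
#' resolve_thresholds("zscore",
#'   list(AP = c(mean = 1.34, sd = 0.17), jAP = c(mean = 0.99, sd = 0.14)))
resolve_thresholds <- function(mode = c("absolute", "zscore"), reference,
                               jlh_elevated_mm = 5, n_sd = 2) {
  mode <- match.arg(mode)
  if (mode == "absolute") {
    if (is.null(reference$ap_low) || is.null(reference$jap_low))
      stop("absolute mode needs 'ap_low' and 'jap_low' cutoffs",
           call. = FALSE)
    return(baja_thresholds(reference$ap_low, reference$jap_low,
                           if (!is.null(reference$jlh_elevated_mm))
                             reference$jlh_elevated_mm else jlh_elevated_mm))
  }
  ms <- function(index) {
    if (is.data.frame(reference)) {
      if (!index %in% names(reference))
        stop(sprintf("reference cohort lacks an '%s' column", index),
             call. = FALSE)
      v <- reference[[index]]
      if (length(v) < 10)
        stop(sprintf(paste0("insufficient reference: %d case(s); at least 10 ",
                            "are needed to estimate a normal range"),
                     length(v)), call. = FALSE)
      c(mean = mean(v), sd = stats::sd(v))
    } else {
      v <- reference[[index]]
      if (is.null(v) || is.na(v["mean"]) || is.na(v["sd"]))
        stop(sprintf("reference summary for '%s' needs 'mean' and 'sd'",
                     index), call. = FALSE)
      v
    }
  }
  ap <- ms("AP"); jap <- ms("jAP")
  baja_thresholds(unname(ap["mean"] - n_sd * ap["sd"]),
                  unname(jap["mean"] - n_sd * jap["sd"]),
                  jlh_elevated_mm)
}

#' Classify true versus pseudo patella baja
#'
#' Rule-based discrimination from a paired pre/post case:
#' \itemize{
#'   \item AP low AND jAP low: \strong{true_baja} - the patella itself sits
#'     low (shortened tendon), so both axis-referenced indices fall.
#'   \item AP normal AND jAP low AND JLH elevated by at least
#'     `jlh_elevated_mm`: \strong{pseudo_baja} - the patella is where it was
#'     (AP normal, T1 being surgery-independent) but the joint line rose to
#'     meet it.
#'   \item AP normal AND jAP normal: \strong{normal}.
#'   \item anything else: \strong{indeterminate}, with the evidence recorded.
#' }
#' Without a preoperative panel the JLH difference is unavailable, so
#' pseudo_baja is unreachable; the call is then restricted and flagged.
#'
#' @param pair A [paired_deltas()] result, or a postoperative `index_panel`
#'   (restricted mode).
#' @param thresholds A [baja_thresholds()] object.
#' @return An object of class `baja_call`: `label`, `evidence` (named
#'   logicals `ap_low`, `jap_low`, `jlh_elevated`), `thresholds`,
#'   `restricted`.
#' @export
classify_baja <- function(pair, thresholds) {
  stopifnot(inherits(thresholds, "baja_thresholds"))
  restricted <- FALSE
  if (inherits(pair, "paired_case")) {
    post <- pair$post
    d_jlh <- pair$deltas[["JLH"]]
  } else if (inherits(pair, "index_panel")) {
    if (pair$phase != "post")
      stop("classification needs the postoperative panel", call. = FALSE)
    post <- pair
    d_jlh <- NA_real_
    restricted <- TRUE
  } else {
    stop("'pair' must be a paired_case or a postoperative index_panel",
         call. = FALSE)
  }

  ev <- c(ap_low = post$AP < thresholds$ap_low,
          jap_low = post$jAP < thresholds$jap_low,
          jlh_elevated = !is.na(d_jlh) &&
            d_jlh >= thresholds$jlh_elevated_mm)

  label <- if (ev[["ap_low"]] && ev[["jap_low"]]) "true_baja"
  else if (!ev[["ap_low"]] && ev[["jap_low"]] && ev[["jlh_elevated"]])
    "pseudo_baja"
  else if (!ev[["ap_low"]] && !ev[["jap_low"]]) "normal"
  else "indeterminate"

  structure(list(case_id = post$case_id, label = label, evidence = ev,
                 delta_jlh = d_jlh, thresholds = thresholds,
                 restricted = restricted),
            class = "baja_call")
}

#' @export
print.baja_call <- function(x, ...) {
  cat(sprintf("<baja_call> case %s: %s%s\n", x$case_id, x$label,
              if (x$restricted) " (restricted: no preoperative panel)" else ""))
  cat(sprintf("  AP low: %s; jAP low: %s; JLH elevated: %s (dJLH %s mm)\n",
              x$evidence[["ap_low"]], x$evidence[["jap_low"]],
              x$evidence[["jlh_elevated"]],
              if (is.na(x$delta_jlh)) "NA" else
                sprintf("%+.2f", x$delta_jlh)))
  invisible(x)
}
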