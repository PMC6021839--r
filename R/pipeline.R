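## Controller: route one touching blob through the detector-box route first;
## on any fallback signal or failed quality gate, run the shape route. Also
## houses the pixel-identity accuracy metric and a thin batch driver.

## run the shape route, trying hole sources in the fixed order
## natural -> erosion -> skeleton; returns list(line, module_used) or raises
shape_route <- function(mask, shape_cfg = shape_config()) {
  outline <- extract_outline(mask)
  cps <- tryCatch({
    series <- build_series(outline)
    final_cps(candidate_cps(series), series, shape_cfg)
  }, touchsplit_error_DEGENERATE_HULL = function(e) list())
  sources <- list(
    shape_natural = function() find_natural_holes(mask),
    shape_erosion = function() holes_by_erosion(mask, shape_cfg),
    shape_skeleton = function() {
      h <- tryCatch(hole_by_skeleton(mask, shape_cfg, outline = outline),
                    touchsplit_error_DEGENERATE_SHAPE = function(e) NULL)
      if (is.null(h)) list() else list(h)
    }
  )
  last_err <- NULL
  for (nm in names(sources)) {
    holes <- sources[[nm]]()
    if (!length(holes)) next
    gl <- guideline_from_holes(holes)
    line <- tryCatch(boundary_from_shape(gl, cps, outline, mask),
                     touchsplit_error = function(e) { last_err <<- e; NULL })
    if (!is.null(line)) return(list(line = line, module_used = nm))
  }
  ts_error("UNSEPARABLE",
           paste0("shape route exhausted all hole sources",
                  if (!is.null(last_err)) paste0(": ", conditionMessage(last_err)) else ""))
}

## run the detector-box route; returns list(line, module_used, flags) or a
## fallback signal. If gate = FALSE the quality gate is reported but ignored
## (single-route evaluation mode).
bb_route <- function(mask, bbs, bb_cfg = bb_config(), gate = TRUE) {
  flags <- list(n_candidates = length(bbs), n_useful = 0L,
                length_ok = NA, ratio_ok = NA)
  if (!length(bbs)) return(list(signal = fallback("no candidate boxes"), flags = flags))
  roi <- build_roi(mask, bb_cfg)
  kept <- filter_candidates(bbs, roi, bb_cfg)
  if (!length(kept)) return(list(signal = fallback("no box inside the RoI"), flags = flags))
  ubbs <- lapply(kept, evaluate_bb, mask = mask, roi = roi, cfg = bb_cfg)
  useful <- select_useful_bbs(ubbs, roi, mask)
  flags$n_useful <- length(useful)
  if (!length(useful)) return(list(signal = fallback("no useful box"), flags = flags))
  if (length(useful) == 1L) {
    line <- cut_with_one_bb(useful[[1]], mask)
    used <- "bb_one"
  } else {
    line <- cut_with_two_bbs(useful[[1]], useful[[2]], mask)
    used <- "bb_two"
  }
  if (is_fallback(line)) return(list(signal = line, flags = flags))
  labels <- tryCatch(split_by_line(mask, line),
                     touchsplit_error_BAD_CUT = function(e) NULL)
  if (is.null(labels)) {
    return(list(signal = fallback("box cut does not sever the blob"), flags = flags))
  }
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  flags$length_ok <- line$length <= bb_cfg$seg_length_th
  flags$ratio_ok <- max(n1, n2) / min(n1, n2) <= bb_cfg$seg_size_th
  if (gate && !(flags$length_ok && flags$ratio_ok)) {
    return(list(signal = fallback("quality gate failed"), flags = flags))
  }
  list(line = line, labels = labels, module_used = used, flags = flags)
}

#' Separate one touching blob into two labelled instances
#'
#' The detector-box route is tried first (filter, score, select, cut, quality
#' gate); any fallback signal sends the blob to the shape route (natural,
#' erosion or skeleton holes, guideline, concave points).
#'
#' @param mask binary matrix, one 8-connected touching blob.
#' @param bbs list of [bbox()] candidate boxes (may be empty).
#' @param bb_cfg a [bb_config()].
#' @param shape_cfg a [shape_config()].
#' @param mode `"hybrid"` (default), `"bb"` (box route only; the quality gate
#'   is recorded but not enforced), or `"shape"` (shape route only).
#' @return object of class `ts_segmentation`: `labels` (0/1/2 matrix),
#'   `module_used`, `boundary` (`ts_boundary`), `quality_flags`.
#' @export
separate <- function(mask, bbs = list(), bb_cfg = bb_config(),
                     shape_cfg = shape_config(),
                     mode = c("hybrid", "bb", "shape")) {
  mode <- match.arg(mode)
  mask <- as_mask(mask)
  flags <- NULL
  if (mode %in% c("hybrid", "bb")) {
    res <- bb_route(mask, bbs, bb_cfg, gate = (mode == "hybrid"))
    flags <- res$flags
    if (is.null(res$signal)) {
      return(structure(list(labels = res$labels, module_used = res$module_used,
                            boundary = res$line, quality_flags = res$flags),
                       class = "ts_segmentation"))
    }
    if (mode == "bb") {
      ts_error("UNSEPARABLE", paste0("box route failed: ", res$signal$reason))
    }
  }
  sr <- shape_route(mask, shape_cfg)
  labels <- split_by_line(mask, sr$line)
  structure(list(labels = labels, module_used = sr$module_used,
                 boundary = sr$line,
                 quality_flags = c(flags, list(shape_fallback = TRUE))),
            class = "ts_segmentation")
}

#' @export
print.ts_segmentation <- function(x, ...) {
  n1 <- sum(x$labels == 1L); n2 <- sum(x$labels == 2L)
  cat(sprintf("<segmentation: %s, parts %d/%d, boundary %d px>\n",
              x$module_used, n1, n2, x$boundary$length))
  invisible(x)
}

#' Pixel-identity accuracy against ground truth
#'
#' Accuracy is the fraction of ground-truth foreground pixels carrying the
#' correct instance identity, maximized over the two label permutations. An
#' accuracy below `switch_threshold` marks a potential identity switch.
#'
#' @param pred,truth label matrices with values 0/1/2 and identical
#'   dimensions.
#' @param switch_threshold identity-switch rule (default 0.85).
#' @return object of class `ts_eval`: `accuracy`, `id_switch`, `pixels`
#'   (per-label counts of `pred`).
#' @export
pixel_id_accuracy <- function(pred, truth, switch_threshold = 0.85) {
  if (!all(dim(pred) == dim(truth))) {
    ts_error("DIM_MISMATCH", "prediction and truth must share dimensions")
  }
  fg <- truth != 0L
  nfg <- sum(fg)
  direct <- sum(pred[fg] == truth[fg])
  swapped <- sum(pred[fg] == (3L - truth[fg]))
  acc <- max(direct, swapped) / nfg
  structure(list(accuracy = acc, id_switch = acc < switch_threshold,
                 pixels = c(bg = sum(pred == 0L), id1 = sum(pred == 1L),
                            id2 = sum(pred == 2L))),
            class = "ts_eval")
}

#' Batch separation over a list of fixtures
#'
#' @param inputs list; each element needs `mask` and `bbs`, optionally
#'   `truth` for accuracy scoring (a [gen_pair()] fixture works as is).
#' @param bb_cfg,shape_cfg configurations passed to [separate()].
#' @param mode routing mode passed to [separate()].
#' @return list of class `ts_batch`: `per_item` data frame (module, boundary
#'   length, accuracy, error), `summary` (n, n_ok, mean accuracy, module
#'   usage counts).
#' @export
run_batch <- function(inputs, bb_cfg = bb_config(), shape_cfg = shape_config(),
                      mode = "hybrid") {
  n <- length(inputs)
  per <- data.frame(item = seq_len(n),
                    module_used = rep(NA_character_, n),
                    boundary_length = rep(NA_integer_, n),
                    accuracy = rep(NA_real_, n),
                    error = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    x <- inputs[[i]]
    res <- tryCatch(separate(x$mask, x$bbs, bb_cfg, shape_cfg, mode = mode),
                    error = function(e) e)
    if (inherits(res, "error")) {
      per$error[i] <- conditionMessage(res)
      if (!is.null(x$truth)) {
        ## an unseparated blob keeps one identity: score the all-one labelling
        pred <- matrix(ifelse(as_mask(x$mask) != 0, 1L, 0L),
                       nrow(x$mask), ncol(x$mask))
        per$accuracy[i] <- pixel_id_accuracy(pred, x$truth)$accuracy
      }
      next
    }
    per$module_used[i] <- res$module_used
    per$boundary_length[i] <- res$boundary$length
    if (!is.null(x$truth)) {
      per$accuracy[i] <- pixel_id_accuracy(res$labels, x$truth)$accuracy
    }
  }
  usage <- table(factor(per$module_used,
                        levels = c("bb_one", "bb_two", "shape_natural",
                                   "shape_erosion", "shape_skeleton")))
  structure(list(per_item = per,
                 summary = list(n = n, n_ok = sum(is.na(per$error)),
                                mean_accuracy = if (all(is.na(per$accuracy))) NA_real_
                                                else mean(per$accuracy, na.rm = TRUE),
                                module_usage = as.list(usage))),
            class = "ts_batch")
}
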