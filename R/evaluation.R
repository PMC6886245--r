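#' Evaluation counts
#'
#' @param tp,fp,fn non-negative true-positive / false-positive /
#'   false-negative span counts.
#' @return list of class `eval_counts`.
#' @export
eval_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)), class = "eval_counts")
}

check_no_overlap <- function(spans, what) {
  if (nrow(spans) < 2L) return(invisible())
  o <- order(spans$start)
  s <- spans[o, , drop = FALSE]
  if (any(s$start[-1L] <= s$end[-nrow(s)])) {
    stop("overlapping spans in ", what, " list")
  }
  invisible()
}

#' Count exact span matches
#'
#' Strict span-level matching: a predicted span is a true positive only if
#' its start, end and entity type all equal a gold span's. Remaining
#' predictions are false positives; remaining gold spans false negatives.
#'
#' @param gold,pred span data.frames as returned by [tags_to_spans()], each
#'   internally non-overlapping.
#' @return An [eval_counts()] object.
#' @export
match_spans <- function(gold, pred) {
  check_no_overlap(gold, "gold")
  check_no_overlap(pred, "predicted")
  key <- function(s) if (nrow(s)) paste(s$start, s$end, s$type) else character()
  tp <- length(intersect(key(gold), key(pred)))
  eval_counts(tp, nrow(pred) - tp, nrow(gold) - tp)
}

#' F1 from precision and recall
#'
#' The harmonic mean `2 P R / (P + R)`; 0 when `P + R = 0`.
#'
#' @param p,r precision and recall (any common scale, e.g. percent).
#' @return F1 on the same scale.
#' @export
f1_score <- function(p, r) {
  if (p + r <= 0) return(0)
  2 * p * r / (p + r)
}

#' Precision / recall / F1 report
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`,
#' reported as percentages at full precision (the print method shows 3
#' decimals). A zero denominator yields 0 for that metric, with
#' `zero_division = TRUE` flagged in the report.
#'
#' @param counts an [eval_counts()] object.
#' @return list of class `eval_report` with `precision`, `recall`, `f1`
#'   (percent), `counts`, `zero_division`.
#' @export
prf <- function(counts) {
  stopifnot(inherits(counts, "eval_counts"))
  zdiv <- FALSE
  div <- function(num, den) {
    if (den == 0) { zdiv <<- TRUE; return(0) }
    100 * num / den
  }
  p <- div(counts$tp, counts$tp + counts$fp)
  r <- div(counts$tp, counts$tp + counts$fn)
  structure(list(precision = p, recall = r, f1 = f1_score(p, r),
                 counts = counts, zero_division = zdiv),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("precision %7.3f%%  recall %7.3f%%  F1 %7.3f%%   (TP %d, FP %d, FN %d)%s\n",
              x$precision, x$recall, x$f1,
              x$counts$tp, x$counts$fp, x$counts$fn,
              if (x$zero_division) "  [zero-division -> 0]" else ""))
  if (!is.null(x$per_type)) {
    for (ty in names(x$per_type)) {
      r <- x$per_type[[ty]]
      cat(sprintf("  %-12s P %7.3f%%  R %7.3f%%  F1 %7.3f%%\n",
                  ty, r$precision, r$recall, r$f1))
    }
  }
  invisible(x)
}

#' Span-level evaluation of a whole corpus
#'
#' Decodes gold and predicted tag sequences into entity spans, pools the
#' exact-match counts over all sentences (micro-average) and reports
#' precision / recall / F1, with a per-entity-type breakdown.
#'
#' @param gold a [ner_corpus()] carrying gold tags.
#' @param pred predictions: a `ner_corpus`, a list of per-sentence tag
#'   character vectors, or a trained `ner_model` (which is run first).
#' @return An `eval_report` with an extra `per_type` element.
#' @export
evaluate_corpus <- function(gold, pred) {
  stopifnot(inherits(gold, "ner_corpus"))
  if (inherits(pred, "ner_model")) pred <- predict_corpus(pred, gold)
  pred_tags <- if (inherits(pred, "ner_corpus")) {
    lapply(pred$sentences, `[[`, "tag")
  } else pred
  if (length(pred_tags) != length(gold$sentences)) {
    stop("gold and predicted sentence counts differ")
  }
  tp <- 0L; fp <- 0L; fn <- 0L
  by_type <- list()
  bump <- function(ty, field, k) {
    if (is.null(by_type[[ty]])) by_type[[ty]] <<- c(tp = 0L, fp = 0L, fn = 0L)
    by_type[[ty]][[field]] <<- by_type[[ty]][[field]] + k
  }
  for (i in seq_along(gold$sentences)) {
    gt <- gold$sentences[[i]]$tag
    pt <- pred_tags[[i]]
    if (length(pt) != length(gt)) {
      stop("sentence ", i, ": predicted length ", length(pt),
           " != gold length ", length(gt))
    }
    gs <- tags_to_spans(gt); ps <- tags_to_spans(pt)
    cnt <- match_spans(gs, ps)
    tp <- tp + cnt$tp; fp <- fp + cnt$fp; fn <- fn + cnt$fn
    for (ty in unique(c(gs$type, ps$type))) {
      ct <- match_spans(gs[gs$type == ty, , drop = FALSE],
                        ps[ps$type == ty, , drop = FALSE])
      bump(ty, "tp", ct$tp); bump(ty, "fp", ct$fp); bump(ty, "fn", ct$fn)
    }
  }
  rep <- prf(eval_counts(tp, fp, fn))
  rep$per_type <- lapply(by_type, function(v) {
    prf(eval_counts(v[["tp"]], v[["fp"]], v[["fn"]]))
  })
  rep
}

#' Write an evaluation report as key-value text
#'
#' @param report an `eval_report`.
#' @param path output path; keys are `precision`, `recall`, `f1`, `tp`,
#'   `fp`, `fn` (metrics in percent, full precision).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  lines <- c(sprintf("precision\t%.10g", report$precision),
             sprintf("recall\t%.10g", report$recall),
             sprintf("f1\t%.10g", report$f1),
             sprintf("tp\t%d", report$counts$tp),
             sprintf("fp\t%d", report$counts$fp),
             sprintf("fn\t%d", report$counts$fn))
  writeLines(lines, path)
  invisible(path)
}
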