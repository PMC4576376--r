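# Behaviour classes, labelled intervals and the accept/reject workflow.

#' A set of behaviour classes and labelled intervals
#'
#' Holds the behaviour classes (each with a unique integer code and a
#' display colour), the classified intervals (sample ranges with a
#' provenance of `"matched"` or `"manual"`), the record of rejected
#' intervals, and the pending queue of proposed matches awaiting an
#' accept/reject decision. Class codes are assigned 1..K in creation order;
#' code 0 is reserved for "unlabelled". Intervals are inclusive 1-based
#' sample ranges.
#'
#' @param n_samples length of the series being labelled.
#' @return an empty `label_set`.
#' @export
label_set <- function(n_samples) {
  structure(list(
    n_samples = n_samples,
    classes = data.frame(id = integer(0), name = character(0),
                         colour = character(0)),
    intervals = data.frame(class_id = integer(0), start = integer(0),
                           end = integer(0), provenance = character(0)),
    rejected = data.frame(start = integer(0), end = integer(0)),
    pending = data.frame(id = integer(0), start = integer(0),
                         end = integer(0), similarity = numeric(0),
                         class_id = integer(0))),
    class = "label_set")
}

#' Add a behaviour class
#'
#' @param labels a [label_set].
#' @param name class name.
#' @param colour display colour code.
#' @return the updated label set; the new class receives the next integer
#'   code.
#' @export
add_class <- function(labels, name, colour = NA_character_) {
  stopifnot(inherits(labels, "label_set"))
  if (name %in% labels$classes$name) stop("class '", name, "' already exists")
  id <- nrow(labels$classes) + 1L
  labels$classes <- rbind(labels$classes,
                          data.frame(id = id, name = name, colour = colour))
  labels
}

# union adjacent/overlapping same-class intervals; error on cross-class overlap
normalise_intervals <- function(labels) {
  iv <- labels$intervals
  if (!nrow(iv)) return(labels)
  out <- NULL
  for (cid in unique(iv$class_id)) {
    sub <- iv[iv$class_id == cid, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    merged <- sub[1, , drop = FALSE]
    if (nrow(sub) > 1) for (i in 2:nrow(sub)) {
      last <- nrow(merged)
      if (sub$start[i] <= merged$end[last] + 1) {
        merged$end[last] <- max(merged$end[last], sub$end[i])
        if (merged$provenance[last] != sub$provenance[i]) {
          merged$provenance[last] <- "manual"
        }
      } else {
        merged <- rbind(merged, sub[i, , drop = FALSE])
      }
    }
    out <- rbind(out, merged)
  }
  out <- out[order(out$start), , drop = FALSE]
  if (nrow(out) > 1) {
    ov <- which(out$start[-1] <= out$end[-nrow(out)])
    if (length(ov)) {
      i <- ov[1]
      stop("overlapping labels of different classes: class ",
           out$class_id[i], " [", out$start[i], ", ", out$end[i],
           "] and class ", out$class_id[i + 1], " [", out$start[i + 1],
           ", ", out$end[i + 1], "]")
    }
  }
  rownames(out) <- NULL
  labels$intervals <- out
  labels
}

#' Manually label a sample range
#'
#' Manual labelling is the expert's override: it is allowed even inside a
#' previously rejected region. Adjacent or overlapping intervals of the same
#' class are unioned; overlap with a different class is an error.
#'
#' @param labels a [label_set].
#' @param start,end inclusive 1-based sample range (start <= end, within the
#'   series).
#' @param class_id the class code.
#' @return the updated label set; the interval carries
#'   `provenance = "manual"`.
#' @export
manual_label <- function(labels, start, end, class_id) {
  stopifnot(inherits(labels, "label_set"))
  if (!(class_id %in% labels$classes$id)) stop("unknown class id: ", class_id)
  if (start < 1 || end > labels$n_samples || start > end) {
    stop("label range [", start, ", ", end, "] outside series 1..",
         labels$n_samples)
  }
  labels$intervals <- rbind(labels$intervals,
                            data.frame(class_id = as.integer(class_id),
                                       start = as.integer(start),
                                       end = as.integer(end),
                                       provenance = "manual"))
  normalise_intervals(labels)
}

#' Queue matched intervals for an accept/reject decision
#'
#' Matches overlapping a previously rejected interval, or already classified
#' into the target class, are not re-proposed: re-running the same search
#' leaves settled decisions alone.
#'
#' @param labels a [label_set].
#' @param matches a `match_results` data frame from [extract_matches] or
#'   [boost].
#' @param class_id the class the matches are proposed for.
#' @return the updated label set with the surviving matches in the pending
#'   queue.
#' @export
propose_matches <- function(labels, matches, class_id) {
  stopifnot(inherits(labels, "label_set"))
  if (!(class_id %in% labels$classes$id)) stop("unknown class id: ", class_id)
  if (!nrow(matches)) return(labels)
  iv <- data.frame(start = matches$start,
                   end = matches$start + matches$length - 1L,
                   similarity = matches$similarity)
  settled <- rbind(labels$rejected[, c("start", "end")],
                   labels$intervals[labels$intervals$class_id == class_id,
                                    c("start", "end")])
  if (nrow(settled)) {
    hit <- vapply(seq_len(nrow(iv)), function(i) {
      any(iv$start[i] <= settled$end & iv$end[i] >= settled$start)
    }, logical(1))
    iv <- iv[!hit, , drop = FALSE]
  }
  if (nrow(iv)) {
    base <- if (nrow(labels$pending)) max(labels$pending$id) else 0L
    labels$pending <- rbind(labels$pending,
                            data.frame(id = base + seq_len(nrow(iv)),
                                       start = as.integer(iv$start),
                                       end = as.integer(iv$end),
                                       similarity = iv$similarity,
                                       class_id = as.integer(class_id)))
  }
  labels
}

#' Accept or reject pending matches
#'
#' Accepted matches become classified intervals (`provenance = "matched"`);
#' rejected ones are recorded so identical intervals are never auto-accepted
#' again. Rectangular time-regions can be rejected wholesale. The aim of the
#' interactive loop is to keep deciding until the pending queue is empty.
#'
#' @param labels a [label_set].
#' @param accept,reject pending-queue ids to accept / reject.
#' @param reject_regions optional data frame of `start`, `end` sample ranges;
#'   any pending match overlapping one is rejected.
#' @return the updated label set.
#' @export
accept_reject <- function(labels, accept = integer(0), reject = integer(0),
                          reject_regions = NULL) {
  stopifnot(inherits(labels, "label_set"))
  pend <- labels$pending
  unknown <- setdiff(c(accept, reject), pend$id)
  if (length(unknown)) stop("unknown pending id(s): ", paste(unknown, collapse = ", "))
  if (!is.null(reject_regions) && NROW(reject_regions) && nrow(pend)) {
    hit <- vapply(seq_len(nrow(pend)), function(i) {
      any(pend$start[i] <= reject_regions$end &
            pend$end[i] >= reject_regions$start)
    }, logical(1))
    reject <- union(reject, pend$id[hit])
  }
  reject <- setdiff(reject, accept)
  acc <- pend[pend$id %in% accept, , drop = FALSE]
  rej <- pend[pend$id %in% reject, , drop = FALSE]
  if (nrow(acc)) {
    labels$intervals <- rbind(labels$intervals,
                              data.frame(class_id = acc$class_id,
                                         start = acc$start, end = acc$end,
                                         provenance = "matched"))
    labels <- normalise_intervals(labels)
  }
  if (nrow(rej)) {
    labels$rejected <- rbind(labels$rejected,
                             data.frame(start = rej$start, end = rej$end))
  }
  labels$pending <- pend[!(pend$id %in% c(accept, reject)), , drop = FALSE]
  labels
}

#' Per-sample behaviour codes
#'
#' @param labels a [label_set] or `NULL`.
#' @param n number of samples.
#' @return integer vector: each sample inside a labelled interval carries
#'   its class code, all others 0.
#' @export
behaviour_codes <- function(labels, n) {
  codes <- integer(n)
  if (is.null(labels)) return(codes)
  stopifnot(inherits(labels, "label_set"))
  labels <- normalise_intervals(labels)
  iv <- labels$intervals
  for (i in seq_len(nrow(iv))) {
    if (iv$start[i] < 1 || iv$end[i] > n) {
      stop("label interval [", iv$start[i], ", ", iv$end[i],
           "] outside table rows 1..", n)
    }
    codes[iv$start[i]:iv$end[i]] <- iv$class_id[i]
  }
  codes
}

#' Write a label set to CSV
#'
#' One row per classified interval: class id and name, start/end timestamps
#' (ms) and sample indices, similarity (blank for manual labels) and
#' provenance.
#'
#' @param labels a [label_set].
#' @param path output file.
#' @param time_ms optional per-sample timestamps used to report start/end in
#'   milliseconds.
#' @export
write_labels <- function(labels, path, time_ms = NULL) {
  stopifnot(inherits(labels, "label_set"))
  iv <- labels$intervals
  nm <- labels$classes$name[match(iv$class_id, labels$classes$id)]
  df <- data.frame(class_id = iv$class_id, class_name = nm,
                   start = iv$start, end = iv$end,
                   start_ms = if (is.null(time_ms)) NA_real_ else time_ms[iv$start],
                   end_ms = if (is.null(time_ms)) NA_real_ else time_ms[iv$end],
                   provenance = iv$provenance)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.label_set <- function(x, ...) {
  cat("<label_set> ", nrow(x$classes), " classes, ", nrow(x$intervals),
      " intervals, ", nrow(x$pending), " pending, ", nrow(x$rejected),
      " rejected\n", sep = "")
  if (nrow(x$classes)) {
    counts <- table(factor(x$intervals$class_id, levels = x$classes$id))
    for (i in seq_len(nrow(x$classes))) {
      cat("  [", x$classes$id[i], "] ", x$classes$name[i], ": ",
          counts[i], " interval(s)\n", sep = "")
    }
  }
  invisible(x)
}
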