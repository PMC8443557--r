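#' Merge multisyllabic call sequences into bouts
#'
#' Consecutive calls separated by at most `max_gap_s` of silence are merged
#' into a single bout. A bout mixing phee and trill syllables is labeled
#' with the compound category `"phee-trill/trill-phee"`; otherwise the bout
#' takes the modal syllable type (ties broken by first occurrence within
#' the bout).
#'
#' @param raw_calls Data frame with `onset_s`, optional `offset_s`, and
#'   `call_type`; rows must be time-ordered.
#' @param max_gap_s Maximum silent gap within a bout, in seconds. The
#'   default 0.05 s tolerates annotation jitter around a truly gap-free
#'   sequence.
#' @return Data frame of bouts (`onset_s`, `offset_s`, `call_type`,
#'   `n_syllables`).
#' @export
merge_bouts <- function(raw_calls, max_gap_s = 0.05) {
  stopifnot(all(c("onset_s", "call_type") %in% names(raw_calls)))
  n <- nrow(raw_calls)
  if (n == 0)
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      call_type = character(0), n_syllables = integer(0)))
  if (is.unsorted(raw_calls$onset_s)) stop("calls must be time-ordered")
  offset <- raw_calls$offset_s %||% raw_calls$onset_s
  gap <- raw_calls$onset_s[-1] - offset[-n]
  bout_id <- cumsum(c(1, as.integer(gap > max_gap_s)))
  bout_label <- function(types) {
    if (all(c("phee", "trill") %in% types)) return("phee-trill/trill-phee")
    counts <- table(types)
    modal <- names(counts)[counts == max(counts)]
    types[types %in% modal][1]  # tie -> first occurrence in the bout
  }
  out <- do.call(rbind, lapply(split(seq_len(n), bout_id), function(i) {
    data.frame(onset_s = raw_calls$onset_s[i[1]],
               offset_s = offset[i[length(i)]],
               call_type = bout_label(raw_calls$call_type[i]),
               n_syllables = length(i))
  }))
  rownames(out) <- NULL
  out
}

#' Call-type counts and ratios for a session
#'
#' @param table Data frame with a `call_type` column (calls or bouts).
#' @return List with `total_calls`, `counts` (named over the full
#'   vocabulary), and `ratios` (`count / total`; all-`NA` when the session
#'   is empty).
#' @export
call_ratios <- function(table) {
  labels <- call_types()
  unknown <- setdiff(unique(table$call_type), labels)
  if (length(unknown))
    stop("unknown call type(s): ", paste(unknown, collapse = ", "))
  counts <- table(factor(table$call_type, levels = labels))
  total <- sum(counts)
  ratios <- if (total > 0) as.numeric(counts) / total
            else rep(NA_real_, length(labels))
  list(total_calls = as.integer(total),
       counts = stats::setNames(as.integer(counts), labels),
       ratios = stats::setNames(ratios, labels))
}

#' Shannon entropy of a call-type distribution
#'
#' `-sum(r_i * log2(r_i))` with the convention `0 * log 0 = 0`. Maximal
#' (log2 of the number of types) for a uniform repertoire, 0 when a single
#' type dominates completely.
#'
#' @param ratios Call-type ratios summing to 1 within 1e-9.
#' @return Entropy in bits.
#' @export
call_entropy <- function(ratios) {
  r <- as.numeric(ratios)
  if (any(is.na(r))) stop("ratios contain NA (empty session?)")
  if (any(r < 0)) stop("ratios must be non-negative")
  if (abs(sum(r) - 1) > 1e-9) stop("ratios must sum to 1")
  r <- r[r > 0]
  -sum(r * log2(r))
}

#' Summarize one recording session
#'
#' Optionally merges multisyllabic sequences into bouts (the default, so
#' entropy is computed on bouts), then computes counts, ratios and entropy.
#'
#' @param calls Data frame of annotated calls.
#' @param merge Merge into bouts before summarizing?
#' @param max_gap_s Passed to [merge_bouts()].
#' @return List: `total_calls`, `counts`, `ratios`, `entropy_bits` (`NA`
#'   for an empty session).
#' @export
summarize_session <- function(calls, merge = TRUE, max_gap_s = 0.05) {
  tab <- if (merge) merge_bouts(calls, max_gap_s) else calls
  cr <- call_ratios(tab)
  cr$entropy_bits <- if (cr$total_calls > 0) call_entropy(cr$ratios)
                     else NA_real_
  cr
}

#' Average per-animal call entropy across sessions
#'
#' Computes session entropies and averages them per animal, the granularity
#' at which group comparisons of repertoire entropy are made (sessions from
#' weeks 11-13 of age in the reference design).
#'
#' @param calls Data frame with `onset_s`, `call_type`, `animal` and
#'   `session` columns.
#' @param merge,max_gap_s Passed to [summarize_session()].
#' @return Data frame: `animal`, `n_sessions`, `entropy_bits` (mean over
#'   sessions with at least one call).
#' @export
animal_entropy <- function(calls, merge = TRUE, max_gap_s = 0.05) {
  stopifnot(all(c("animal", "session") %in% names(calls)))
  out <- do.call(rbind, lapply(split(calls, calls$animal), function(d) {
    ent <- vapply(split(d, d$session), function(s)
      summarize_session(s, merge, max_gap_s)$entropy_bits, numeric(1))
    data.frame(animal = d$animal[1], n_sessions = length(ent),
               entropy_bits = mean(ent, na.rm = TRUE))
  }))
  rownames(out) <- NULL
  out
}
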