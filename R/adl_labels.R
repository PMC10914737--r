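#' Default activity precedence rules
#'
#' When a self-reported entry groups activities that cannot happen
#' concurrently, the activity the person actively engaged in wins and the
#' passive one is dropped. Each row states one directed rule:
#' when `drops` and `keeps` share an entry, only `keeps` survives.
#' The defaults encode toileting over preparing meal / using computer /
#' watching tv / eating, and organizing over using computer. Pairs covered by
#' no rule pass through as genuinely parallel multi-labels (e.g. eating while
#' watching TV).
#'
#' @return A tibble with columns `drops` and `keeps`.
#' @export
default_precedence <- function() {
  tibble::tibble(
    drops = c("preparing meal", "using computer", "watching tv", "eating",
              "using computer"),
    keeps = c("toileting", "toileting", "toileting", "toileting",
              "organizing")
  )
}

#' Map a reported activity name to the ADL registry
#'
#' Reported names are matched case-insensitively after squashing separators;
#' anything not matching one of the 12 registered ADLs becomes `"other"`.
#'
#' @param adls Character vector of reported names.
#' @return Character vector of registry names.
#' @export
canonical_adl <- function(adls) {
  reg <- adl_registry()
  norm <- function(x) gsub("[ _-]+", " ", tolower(trimws(x)))
  idx <- match(norm(adls), norm(reg))
  out <- reg[idx]
  out[is.na(idx)] <- "other"
  out
}

#' Clean one self-reported multi-label entry
#'
#' Applies the label post-processing rules to a single reported interval:
#'
#' 1. Reported names are mapped onto the 12-class registry; unlisted
#'    activities become `"other"`.
#' 2. When `"room transition"` is the first (last) activity of a multi-label
#'    entry, the first (last) `min(30, duration)` seconds are allocated to the
#'    room transition and the remaining activities cover the rest of the
#'    interval.
#' 3. Precedence rules drop passive activities grouped with an actively
#'    engaging one (e.g. preparing meal + toileting keeps only toileting).
#' 4. Whatever remains passes through as a parallel multi-label segment.
#'
#' The union of the returned segments always equals the input interval.
#'
#' @param start,end Entry interval in seconds (`start < end`).
#' @param adls Ordered character vector of reported activity names.
#' @param rules Precedence table, see [default_precedence()].
#' @param transition_s Seconds allocated to a leading/trailing room
#'   transition.
#' @return A tibble with columns `start`, `end`, `adls` (list-column), the
#'   cleaned segments in time order.
#' @export
#' @examples
#' clean_entry(0, 120, c("room transition", "toileting"))
clean_entry <- function(start, end, adls, rules = default_precedence(),
                        transition_s = 30) {
  stopifnot(length(start) == 1, length(end) == 1, start < end,
            length(adls) >= 1)
  reversed <- vapply(seq_len(nrow(rules)), function(i) {
    any(rules$drops == rules$keeps[i] & rules$keeps == rules$drops[i])
  }, logical(1))
  if (any(reversed)) {
    stop("conflicting precedence rules: both members claim precedence",
         call. = FALSE)
  }
  adls <- canonical_adl(adls)
  adls <- unique(adls)
  rt <- "room transition"
  segments <- list()
  seg_start <- start
  seg_end <- end
  rest <- adls
  if (length(adls) > 1 && adls[1] == rt) {
    cut <- min(transition_s, seg_end - seg_start)
    segments <- c(segments, list(list(start = seg_start,
                                      end = seg_start + cut, adls = rt)))
    seg_start <- seg_start + cut
    rest <- setdiff(rest, rt)
  }
  trailing <- NULL
  if (length(rest) > 1 && rest[length(rest)] == rt && seg_end > seg_start) {
    cut <- min(transition_s, seg_end - seg_start)
    trailing <- list(start = seg_end - cut, end = seg_end, adls = rt)
    seg_end <- seg_end - cut
    rest <- setdiff(rest, rt)
  }
  if (seg_end > seg_start && length(rest) > 0) {
    # precedence: drop passive members of known conflicting pairs
    keep <- rest
    for (i in seq_len(nrow(rules))) {
      if (rules$drops[i] %in% keep && rules$keeps[i] %in% keep) {
        keep <- setdiff(keep, rules$drops[i])
      }
    }
    segments <- c(segments, list(list(start = seg_start, end = seg_end,
                                      adls = keep)))
  }
  if (!is.null(trailing)) segments <- c(segments, list(trailing))
  tibble::tibble(
    start = vapply(segments, `[[`, numeric(1), "start"),
    end = vapply(segments, `[[`, numeric(1), "end"),
    adls = lapply(segments, function(s) unname(s$adls))
  )
}

#' Clean all label entries of a session
#'
#' Applies [clean_entry()] to every reported entry. Unknown pairs (multiple
#' activities with no precedence rule and no room transition) pass through as
#' parallel labels with a warning when they are not in the known-parallel set.
#'
#' @param adl_labels Tibble with columns `start`, `end`, `adls` (list-column).
#' @param rules Precedence table.
#' @param transition_s Room-transition allocation in seconds.
#' @return A cleaned label tibble in the same layout.
#' @export
clean_labels <- function(adl_labels, rules = default_precedence(),
                         transition_s = 30) {
  if (nrow(adl_labels) == 0) return(adl_labels)
  out <- lapply(seq_len(nrow(adl_labels)), function(i) {
    clean_entry(adl_labels$start[i], adl_labels$end[i],
                adl_labels$adls[[i]], rules = rules,
                transition_s = transition_s)
  })
  dplyr::bind_rows(out)
}

#' Densify cleaned label segments onto the 3-second grid
#'
#' Produces the dense multi-hot label matrix `Y` (T x 12) and the time-weight
#' vector `w`: `Y[t, c] = 1` when grid point `t` lies inside a segment labeled
#' `c`, and `w[t] = 1` when `t` lies inside any labeled segment (0 =
#' unlabeled; such steps are masked out of the training loss).
#'
#' @param entries Cleaned label tibble (`start`, `end`, `adls`).
#' @param duration Session duration in seconds.
#' @param step_s Grid step (3 s).
#' @return A list of class `"dense_labels"`: `t` (grid), `Y` (T x 12 binary
#'   matrix, columns in [adl_registry()] order), `w` (T numeric 0/1).
#' @export
densify <- function(entries, duration, step_s = 3) {
  reg <- adl_registry()
  t_grid <- seq(0, duration - step_s + 1e-9, by = step_s)
  Y <- matrix(0L, length(t_grid), length(reg),
              dimnames = list(NULL, reg))
  w <- numeric(length(t_grid))
  for (i in seq_len(nrow(entries))) {
    inside <- t_grid >= entries$start[i] - 1e-9 & t_grid < entries$end[i] - 1e-9
    if (!any(inside)) next
    cls <- match(canonical_adl(entries$adls[[i]]), reg)
    Y[inside, cls] <- 1L
    w[inside] <- 1
  }
  structure(list(t = t_grid, Y = Y, w = w), class = "dense_labels")
}

#' @export
print.dense_labels <- function(x, ...) {
  cat("<dense_labels>", length(x$t), "steps,", sum(x$w > 0), "labeled\n")
  invisible(x)
}

#' Balanced binary class weights from dense labels
#'
#' For each class `c`, with `L` the total labeled time weight and `P_c` the
#' labeled weight with class `c` positive, the weights
#' `w_pos = L / (2 P_c)` and `w_neg = L / (2 (L - P_c))` balance the positive
#' and negative contributions: `w_pos * P_c + w_neg * (L - P_c) = L`. Classes
#' never observed positive get `w_pos = 1` with a warning (and classes never
#' negative `w_neg = 1`).
#'
#' @param dense A `"dense_labels"` object (or a list of them, pooled).
#' @return A tibble with columns `class`, `w_pos`, `w_neg`.
#' @export
class_weights <- function(dense) {
  if (inherits(dense, "dense_labels")) dense <- list(dense)
  L <- sum(vapply(dense, function(d) sum(d$w), numeric(1)))
  if (L == 0) stop("no labeled time points: cannot compute class weights",
                   call. = FALSE)
  P <- Reduce(`+`, lapply(dense, function(d) colSums(d$w * d$Y)))
  w_pos <- ifelse(P > 0, L / (2 * P), 1)
  w_neg <- ifelse(L - P > 0, L / (2 * (L - P)), 1)
  if (any(P == 0)) {
    warning("class(es) with no positive labeled time: ",
            paste(adl_registry()[P == 0], collapse = ", "),
            "; w_pos set to 1")
  }
  tibble::tibble(class = adl_registry(), w_pos = unname(w_pos),
                 w_neg = unname(w_neg))
}
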