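# Narrative-shift coding.
#
# A narrative shift is a change in location (L), major characters (C), and/or
# time (T) across a pair of adjacent shots. Seven shift types exist --
# [L C T], [L C -], [L - T], [L - -], [- C T], [- C -], [- - T] -- with
# [- - -] denoting the within-scene juxtaposition of shots.

#' Canonical shift labels
#'
#' @return Character vector of the seven shift labels in canonical order,
#'   followed by the null label `[- - -]`.
#' @export
shift_levels <- function() {
  c("[L C T]", "[L C -]", "[L - T]", "[L - -]",
    "[- C T]", "[- C -]", "[- - T]", "[- - -]")
}

#' Render a (L, C, T) triple as its canonical label
#'
#' @param L,C,T Logicals: did location / major characters / time change?
#' @return A label such as `"[L C -]"`; `"[- - -]"` iff all three are FALSE.
#' @export
shift_label <- function(L, C, T) {
  paste0("[", ifelse(L, "L", "-"), " ", ifelse(C, "C", "-"), " ",
         ifelse(T, "T", "-"), "]")
}

#' Major characters of a movie
#'
#' A major character is one appearing in strictly more than 10% of the
#' movie's shots; only major characters count towards character shifts.
#'
#' @param movie A `movie_annotation`.
#' @param threshold Appearance share above which a character is major
#'   (default 0.10, strict inequality).
#' @return Character vector of major-character labels (possibly empty).
#' @export
major_characters <- function(movie, threshold = 0.10) {
  counts <- table(unlist(movie$shots$characters))
  if (length(counts) == 0) return(character(0))
  sort(names(counts)[counts > threshold * n_shots(movie)])
}

#' Code the narrative shift across one shot boundary
#'
#' Rules:
#' * L: the location label differs across the boundary.
#' * C: the major-character sets differ (present-to-absent transitions count;
#'   when both shots have no major characters the character code is null).
#' * T: an explicit time mark on the incoming shot wins (`forward_ellipsis` or
#'   `backward` force T, `continuous` forces no-T). With `auto`, time is
#'   inferred: the same (non-empty) major characters shown in a changed
#'   location implies a time change (unless the move is an instantaneous
#'   teleport), while cross-cuts (location and characters both change),
#'   character-free location changes, and static junctures run on continuous
#'   time.
#'
#' @param prev,next_ Adjacent shot rows (1-row data frames or lists with the
#'   shot fields).
#' @param majors Character vector from [major_characters()].
#' @return List with logicals `L`, `C`, `T`, the canonical `label`, and a
#'   `derivation` string saying whether T came from an explicit mark or which
#'   inference rule fired.
#' @export
code_boundary <- function(prev, next_, majors) {
  get1 <- function(shot, field) {
    v <- shot[[field]]
    if (is.list(v) && field != "characters") v <- v[[1]]
    if (field == "characters" && is.list(v)) v <- v[[1]]
    v
  }
  chars <- function(shot) {
    ch <- get1(shot, "characters")
    if (is.null(ch)) character(0) else as.character(ch)
  }
  L <- !identical(as.character(get1(prev, "location_id")),
                  as.character(get1(next_, "location_id")))
  m_prev <- sort(intersect(chars(prev), majors))
  m_next <- sort(intersect(chars(next_), majors))
  C <- if (length(m_prev) == 0 && length(m_next) == 0) FALSE
       else !identical(m_prev, m_next)

  mark <- as.character(get1(next_, "time_mark_in"))
  if (!mark %in% TIME_MARKS)
    annot_error("unknown time_mark_in '%s'", mark)
  teleport <- isTRUE(get1(next_, "teleport_in"))
  if (mark == "forward_ellipsis" || mark == "backward") {
    T <- TRUE
    derivation <- paste0("T: explicit mark (", mark, ")")
  } else if (mark == "continuous") {
    T <- FALSE
    derivation <- "T: explicit mark (continuous)"
  } else if (L && !C && length(m_prev) > 0 && !teleport) {
    T <- TRUE
    derivation <- "T: inferred (same characters, changed location)"
  } else if (L && !C && length(m_prev) > 0 && teleport) {
    T <- FALSE
    derivation <- "T: inferred (teleport exception)"
  } else if (L && !C) {
    T <- FALSE
    derivation <- "T: inferred (no major characters shown, no time commitment)"
  } else if (L && C) {
    T <- FALSE
    derivation <- "T: inferred (cross-cut, time continuous)"
  } else {
    T <- FALSE
    derivation <- "T: inferred (no location change, time continuous)"
  }
  list(L = L, C = C, T = T, label = shift_label(L, C, T),
       derivation = derivation)
}

#' Code every shot boundary of a movie
#'
#' @param movie A `movie_annotation`.
#' @return Tibble with one row per juncture: `boundary_index` (boundary `i`
#'   lies between shots `i` and `i + 1`), logicals `L`, `C`, `T`, the
#'   canonical `label`, and the `derivation` of the time code.
#' @export
code_movie <- function(movie) {
  validate_movie(movie)
  majors <- major_characters(movie)
  s <- movie$shots
  n <- nrow(s)
  out <- lapply(seq_len(n - 1), function(i) {
    code_boundary(s[i, ], s[i + 1, ], majors)
  })
  tibble::tibble(
    boundary_index = seq_len(n - 1),
    L = vapply(out, `[[`, TRUE, "L"),
    C = vapply(out, `[[`, TRUE, "C"),
    T = vapply(out, `[[`, TRUE, "T"),
    label = vapply(out, `[[`, "", "label"),
    derivation = vapply(out, `[[`, "", "derivation")
  )
}

#' Relative frequencies of the seven shift types
#'
#' Tallies non-null shift labels as percentages. The null label `[- - -]` is
#' excluded from the denominator: the distribution describes narrative shifts,
#' not all junctures.
#'
#' @param codes Tibble from [code_movie()] (or several movies' codes bound
#'   together).
#' @param mask Optional logical vector (or integer indices) selecting the
#'   boundaries to tally.
#' @return Tibble with `label` (the seven shift types, canonical order),
#'   `n`, and `percent` (summing to 100 up to rounding).
#' @export
shift_distribution <- function(codes, mask = NULL) {
  labels <- codes$label
  if (!is.null(mask)) labels <- labels[mask]
  labels <- labels[labels != "[- - -]"]
  if (length(labels) == 0)
    stop("empty selection: no narrative shifts to tally")
  lv <- shift_levels()[1:7]
  n <- as.integer(table(factor(labels, levels = lv)))
  tibble::tibble(label = lv, n = n, percent = 100 * n / sum(n))
}
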