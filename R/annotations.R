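#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test median pf pnorm pt pchisq rbinom rnorm rpois
#'   runif lm coef vcov resid setNames complete.cases sd t.test as.formula qlogis plogis
#' @importFrom utils read.csv write.csv head
NULL

# ---- enumerations shared across the package -------------------------------

TRANSITIONS <- c("cut", "dissolve", "fade", "wipe", "none")
TIME_MARKS <- c("auto", "continuous", "forward_ellipsis", "backward")
SOUND_CLASSES <- c("nondiegetic_music", "diegetic_music", "voiceover",
                   "ambient_signal", "none")
GENRES <- c("action", "comedy", "drama")

#' Construct a validated movie annotation
#'
#' A movie annotation is the unit of input for the whole pipeline: an ordered
#' table of shots with the attributes needed to code narrative shifts (location,
#' characters, explicit time marks) plus duration, framing scale, and sound
#' coverage class.
#'
#' @param movie_id Character label for the movie.
#' @param release_year Integer release year (1900--2100).
#' @param genre One of `"action"`, `"comedy"`, `"drama"`.
#' @param shots A data frame with one row per shot, in order, with columns
#'   `shot_index` (1-based, gapless), `duration_s` (> 0), `scale` (integer
#'   1--7, extreme close-up through extreme long shot), `location_id`
#'   (character), `characters` (list column of character vectors; empty vector
#'   for shots with no characters), `transition_in` (`cut`, `dissolve`, `fade`,
#'   `wipe`; `none` for the first shot), `time_mark_in` (`auto`, `continuous`,
#'   `forward_ellipsis`, `backward`), `teleport_in` (logical), and `sound`
#'   (one of `nondiegetic_music`, `diegetic_music`, `voiceover`,
#'   `ambient_signal`, `none`).
#' @return An object of class `movie_annotation`.
#' @export
movie_annotation <- function(movie_id, release_year, genre, shots) {
  shots <- tibble::as_tibble(shots)
  m <- structure(
    list(movie_id = as.character(movie_id),
         release_year = as.integer(release_year),
         genre = as.character(genre),
         shots = shots),
    class = "movie_annotation"
  )
  validate_movie(m)
  m
}

#' @export
print.movie_annotation <- function(x, ...) {
  cat(sprintf("<movie_annotation> %s (%d, %s): %d shots, %.1f s\n",
              x$movie_id, x$release_year, x$genre,
              n_shots(x), sum(x$shots$duration_s)))
  invisible(x)
}

#' Number of shots in a movie annotation
#' @param movie A `movie_annotation`.
#' @return Integer shot count.
#' @export
n_shots <- function(movie) nrow(movie$shots)

shot_cols <- c("shot_index", "duration_s", "scale", "location_id",
               "characters", "transition_in", "time_mark_in", "teleport_in",
               "sound")

annot_error <- function(fmt, ..., row = NA, field = NA) {
  msg <- sprintf(fmt, ...)
  if (!is.na(row)) msg <- sprintf("row %s, field '%s': %s", row, field, msg)
  stop(structure(class = c("cinevents_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      row = row, field = field)))
}

#' Validate a movie annotation
#'
#' Checks every documented invariant of the annotation dialect and raises a
#' `cinevents_validation_error` naming the offending row and field.
#'
#' @param movie A `movie_annotation`.
#' @return The movie, invisibly, if valid.
#' @export
validate_movie <- function(movie) {
  s <- movie$shots
  missing_cols <- setdiff(shot_cols, names(s))
  if (length(missing_cols) > 0)
    annot_error("missing required column(s): %s",
                paste(missing_cols, collapse = ", "))
  if (nrow(s) < 2) annot_error("a movie needs at least 2 shots")
  if (!is.na(movie$release_year) &&
      (movie$release_year < 1900 || movie$release_year > 2100))
    annot_error("release_year %d outside 1900-2100", movie$release_year)
  if (!movie$genre %in% GENRES)
    annot_error("unknown genre '%s'", movie$genre)
  if (!identical(as.integer(s$shot_index), seq_len(nrow(s))))
    annot_error("shot_index must be 1..n, strictly increasing and gapless")
  bad <- which(!is.finite(s$duration_s) | s$duration_s <= 0)
  if (length(bad) > 0)
    annot_error("duration_s must be > 0 (got %s)", s$duration_s[bad[1]],
                row = bad[1], field = "duration_s")
  bad <- which(!(s$scale %in% 1:7))
  if (length(bad) > 0)
    annot_error("scale must be an integer 1-7", row = bad[1], field = "scale")
  check_enum <- function(field, levels) {
    v <- s[[field]]
    bad <- which(!(v %in% levels))
    if (length(bad) > 0)
      annot_error("'%s' not in {%s}", v[bad[1]], paste(levels, collapse = ", "),
                  row = bad[1], field = field)
  }
  check_enum("transition_in", TRANSITIONS)
  check_enum("time_mark_in", TIME_MARKS)
  check_enum("sound", SOUND_CLASSES)
  if (s$transition_in[1] != "none")
    annot_error("first shot must have transition_in = 'none'",
                row = 1, field = "transition_in")
  if (any(s$transition_in[-1] == "none"))
    annot_error("'none' transition only allowed on the first shot",
                row = which(s$transition_in[-1] == "none")[1] + 1,
                field = "transition_in")
  if (!is.list(s$characters))
    annot_error("characters must be a list column of character vectors")
  if (!is.logical(s$teleport_in) || anyNA(s$teleport_in))
    annot_error("teleport_in must be logical and non-missing")
  invisible(movie)
}

# ---- serialization --------------------------------------------------------

movie_to_list <- function(movie) {
  s <- movie$shots
  list(
    movie_id = movie$movie_id,
    release_year = movie$release_year,
    genre = movie$genre,
    shots = lapply(seq_len(nrow(s)), function(i) {
      list(shot_index = as.integer(s$shot_index[i]),
           duration_s = s$duration_s[i],
           scale = as.integer(s$scale[i]),
           location_id = s$location_id[i],
           # empty character sets serialize as [], never null
           characters = as.list(as.character(s$characters[[i]])),
           transition_in = s$transition_in[i],
           time_mark_in = s$time_mark_in[i],
           teleport_in = s$teleport_in[i],
           sound = s$sound[i])
    })
  )
}

movie_from_list <- function(x) {
  shots <- tibble::tibble(
    shot_index = vapply(x$shots, function(s) as.integer(s$shot_index), 1L),
    duration_s = vapply(x$shots, function(s) as.numeric(s$duration_s), 1.0),
    scale = vapply(x$shots, function(s) as.integer(s$scale), 1L),
    location_id = vapply(x$shots, function(s) as.character(s$location_id), ""),
    characters = lapply(x$shots, function(s) unlist(lapply(s$characters, as.character))),
    transition_in = vapply(x$shots, function(s) as.character(s$transition_in), ""),
    time_mark_in = vapply(x$shots, function(s) as.character(s$time_mark_in), ""),
    teleport_in = vapply(x$shots, function(s) as.logical(s$teleport_in), TRUE),
    sound = vapply(x$shots, function(s) as.character(s$sound), "")
  )
  shots$characters <- lapply(shots$characters, function(ch) {
    if (is.null(ch)) character(0) else ch
  })
  movie_annotation(x$movie_id, x$release_year, x$genre, shots)
}

#' Read a movie annotation from disk
#'
#' Two dialects are supported. JSON is the canonical lossless form (UTF-8,
#' deterministic field order, full double precision). CSV is a flat table with
#' a header row and the `characters` field as semicolon-joined labels.
#'
#' @param path Path to a `movie.json` or `movie.csv` file.
#' @param format `"json"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @return A validated `movie_annotation`.
#' @export
read_movie <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "json") {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(movie_from_list(x))
  }
  df <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- setdiff(setdiff(shot_cols, "characters"), names(df))
  if (length(need) > 0)
    annot_error("missing required column(s): %s", paste(need, collapse = ", "))
  if (!"characters" %in% names(df))
    annot_error("missing required column(s): characters")
  shots <- tibble::as_tibble(df[setdiff(shot_cols, "characters")])
  shots$characters <- lapply(df$characters, function(x) {
    if (is.na(x) || x == "") character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
  })
  shots <- shots[shot_cols]
  shots$teleport_in <- as.logical(shots$teleport_in)
  movie_annotation(df$movie_id[1], df$release_year[1], df$genre[1], shots)
}

#' Write a movie annotation to disk
#'
#' Inverse of [read_movie()]. JSON output has deterministic field order and
#' round-trips bit-exactly: `write_movie(read_movie(p))` reproduces `p` byte
#' for byte.
#'
#' @param movie A validated `movie_annotation`.
#' @param path Output path.
#' @param format `"json"` or `"csv"` (inferred from the extension by default).
#' @return The path, invisibly.
#' @export
write_movie <- function(movie, path, format = c("auto", "json", "csv")) {
  validate_movie(movie)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    json <- jsonlite::toJSON(movie_to_list(movie), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
  } else {
    s <- movie$shots
    df <- data.frame(
      movie_id = movie$movie_id,
      release_year = movie$release_year,
      genre = movie$genre,
      s[setdiff(shot_cols, "characters")],
      characters = vapply(s$characters, paste, "", collapse = ";"),
      stringsAsFactors = FALSE
    )
    df <- df[c("movie_id", "release_year", "genre", shot_cols)]
    write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

# ---- viewer responses -----------------------------------------------------

#' Construct a viewer response table
#'
#' Per-boundary 0/1 segmentation responses for each viewer. Boundary `i` is
#' the juncture between shot `i` and shot `i + 1` (1-based), so a movie with
#' `n` shots has `n - 1` boundaries.
#'
#' @param movie_id Movie label.
#' @param responses Long tibble with columns `boundary_index`, `viewer_id`,
#'   `response` (0/1).
#' @param n_shots Number of shots in the movie (for range validation);
#'   `NA` skips the range check.
#' @return A tibble of class `viewer_responses` with attribute `movie_id`.
#' @export
viewer_responses <- function(movie_id, responses, n_shots = NA) {
  r <- tibble::as_tibble(responses)
  stopifnot(all(c("boundary_index", "viewer_id", "response") %in% names(r)))
  if (!all(r$response %in% c(0L, 1L)))
    annot_error("responses must be 0/1")
  if (!is.na(n_shots) &&
      (any(r$boundary_index < 1) || any(r$boundary_index > n_shots - 1)))
    annot_error("boundary_index outside [1, n_shots - 1]")
  r$movie_id <- as.character(movie_id)
  r <- r[c("movie_id", "boundary_index", "viewer_id", "response")]
  class(r) <- c("viewer_responses", class(r))
  r
}

#' Read / write viewer response tables
#'
#' `responses.csv` has columns `movie_id, boundary_index, viewer_id, response`.
#' Multiple movies may share one file.
#'
#' @param path CSV path.
#' @return `read_responses()`: a `viewer_responses` tibble (possibly spanning
#'   several movies).
#' @export
read_responses <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("movie_id", "boundary_index", "viewer_id", "response") %in% names(df)))
  r <- tibble::as_tibble(df)
  if (!all(r$response %in% c(0L, 1L))) annot_error("responses must be 0/1")
  class(r) <- c("viewer_responses", class(r))
  r
}

#' @rdname read_responses
#' @param responses A `viewer_responses` tibble.
#' @export
write_responses <- function(responses, path) {
  write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' Per-boundary response counts
#'
#' Collapses a viewer response table to one row per boundary with the number
#' of viewers (0..n_viewers) who placed an event boundary there.
#'
#' @param responses A `viewer_responses` tibble.
#' @return Tibble with `movie_id`, `boundary_index`, `count`, `n_viewers`.
#' @export
response_counts <- function(responses) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(responses), movie_id, boundary_index),
    count = sum(response), n_viewers = dplyr::n(), .groups = "drop")
}
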