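#' Read an image metadata table
#'
#' Reads a delimited table describing the stimulus set: one row per image with
#' its material class and exemplar index (the canonical design uses 3 exemplar
#' photographs per material class).
#'
#' @param path Path to a CSV/TSV file with columns `image_id`, `class_label`,
#'   `exemplar_index`.
#' @return A `data.frame` with those three columns; `image_id` unique.
#' @export
read_images <- function(path) {
  df <- .read_delim(path, c("image_id", "class_label", "exemplar_index"))
  df$image_id <- as.character(df$image_id)
  df$class_label <- as.character(df$class_label)
  df$exemplar_index <- as.integer(df$exemplar_index)
  if (anyDuplicated(df$image_id))
    stop("duplicate image_id in ", path, ": ",
         paste(unique(df$image_id[duplicated(df$image_id)]), collapse = ", "))
  df
}

#' Read a triplet 2-AFC trial table
#'
#' One row per behavioral trial: a worker saw a reference image on top and two
#' option images below, and chose the option more similar to the reference.
#' Every image id must exist in the image metadata table; malformed rows are a
#' hard error that names the offending row.
#'
#' @param path Path to a CSV/TSV file with header
#'   `worker_id,reference,option_a,option_b,choice,rt_ms,position`
#'   (`position` optional, the screen position of the chosen option; an
#'   optional `repeat_block` column tags membership in a repeated-triplet
#'   subset used for noise-ceiling estimation).
#' @param images Image metadata as returned by [read_images()].
#' @return A validated trial `data.frame`; row count preserved.
#' @export
read_trials <- function(path, images) {
  req <- c("worker_id", "reference", "option_a", "option_b", "choice", "rt_ms")
  df <- .read_delim(path, req, optional = c("position", "repeat_block"))
  if (nrow(df) == 0L) {
    warning("trial file ", path, " contains a header but no trials")
    return(.as_trials(df))
  }
  df <- .as_trials(df)
  validate_trials(df, images)
  df
}

.read_delim <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "[,\t]")[[1]]
  header <- trimws(header)
  if (anyDuplicated(header))
    stop("duplicate column in header of ", path, ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                 check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  df[, c(required, intersect(optional, names(df))), drop = FALSE]
}

.as_trials <- function(df) {
  for (col in c("worker_id", "reference", "option_a", "option_b", "choice"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  if ("rt_ms" %in% names(df)) df[[("rt_ms")]] <- as.numeric(df[["rt_ms"]])
  df
}

#' Validate a trial table against the image set
#'
#' @param trials Trial `data.frame`.
#' @param images Image metadata (`image_id` column used).
#' @return `trials`, invisibly, if valid; otherwise a hard error naming the
#'   first offending row and image id.
#' @export
validate_trials <- function(trials, images) {
  if (nrow(trials) == 0L) return(invisible(trials))
  known <- images$image_id
  for (col in c("reference", "option_a", "option_b")) {
    bad <- which(!(trials[[col]] %in% known))
    if (length(bad))
      stop("unknown image id \"", trials[[col]][bad[1]], "\" in column ",
           col, ", row ", bad[1])
  }
  same <- trials$reference == trials$option_a |
    trials$reference == trials$option_b |
    trials$option_a == trials$option_b
  if (any(same))
    stop("reference/option_a/option_b not pairwise distinct at row ",
         which(same)[1])
  badc <- which(!(trials$choice %in% c("A", "B")))
  if (length(badc))
    stop("choice must be 'A' or 'B'; offending row ", badc[1])
  if (any(!is.na(trials$rt_ms) & trials$rt_ms < 0))
    stop("negative rt_ms at row ", which(trials$rt_ms < 0)[1])
  invisible(trials)
}

#' Summarize workers for quality control
#'
#' Computes, per worker, the trial count, the fractions of overly fast
#' responses (below 600 ms and below 900 ms), and the fraction of responses
#' at the worker's more-chosen of the two 2-AFC option positions. A worker
#' with any missing response time is flagged `unfilterable` rather than
#' silently passed through the RT rules.
#'
#' @param trials Trial `data.frame` (needs `rt_ms`; `position` optional).
#' @return A `data.frame` with one row per worker: `worker_id`, `n_trials`,
#'   `frac_rt_below_600`, `frac_rt_below_900`, `frac_position_majority`
#'   (NA when position was not recorded), `unfilterable`.
#' @export
summarize_workers <- function(trials) {
  stopifnot("rt_ms" %in% names(trials))
  dt <- data.table::as.data.table(trials)
  has_pos <- "position" %in% names(dt)
  summ <- dt[, {
    rt <- rt_ms
    n <- .N
    unf <- anyNA(rt)
    f600 <- if (unf) NA_real_ else mean(rt < 600)
    f900 <- if (unf) NA_real_ else mean(rt < 900)
    fpos <- NA_real_
    if (has_pos) {
      p <- position[!is.na(position)]
      if (length(p) == n && n > 0) {
        tab <- table(factor(p, levels = c("left", "right")))
        fpos <- max(tab) / n
      }
    }
    list(n_trials = n, frac_rt_below_600 = f600, frac_rt_below_900 = f900,
         frac_position_majority = fpos, unfilterable = unf)
  }, by = worker_id]
  out <- as.data.frame(summ)
  out[order(out$worker_id), , drop = FALSE]
}

#' Apply the worker exclusion rules
#'
#' A worker is excluded iff
#' (`n_trials >= 60` and (`frac_rt_below_600 > 0.25` or
#' `frac_rt_below_900 > 0.50`)) or
#' (`n_trials >= 160` and `frac_position_majority > 0.60`).
#' All inequalities on the fractions are strict; boundary workers are kept.
#' Exclusion is worker-level: every trial of an excluded worker is dropped.
#' Workers without position data are exempt from the position rule (with a
#' warning) but remain subject to the RT rules.
#'
#' @param trials Trial `data.frame`.
#' @param summaries Output of [summarize_workers()] computed on `trials`
#'   (computed internally when omitted).
#' @return A list with `trials` (kept rows, original order), and `report`: a
#'   `data.frame` of excluded workers with the rule(s) they hit, plus
#'   attributes `n_excluded_trials`, `n_total_trials`, `pct_excluded`
#'   (formatted percentage string, e.g. `"9.19%"`).
#' @export
exclude_workers <- function(trials, summaries = summarize_workers(trials)) {
  s <- summaries
  if (any(s$unfilterable))
    warning("worker(s) with missing response times are unfilterable: ",
            paste(s$worker_id[s$unfilterable], collapse = ", "))
  if (any(is.na(s$frac_position_majority) & s$n_trials >= 160))
    warning("worker(s) without position data exempt from the position rule: ",
            paste(s$worker_id[is.na(s$frac_position_majority) &
                                s$n_trials >= 160], collapse = ", "))
  rt_rule <- s$n_trials >= 60 &
    ((!is.na(s$frac_rt_below_600) & s$frac_rt_below_600 > 0.25) |
       (!is.na(s$frac_rt_below_900) & s$frac_rt_below_900 > 0.50))
  pos_rule <- s$n_trials >= 160 &
    !is.na(s$frac_position_majority) & s$frac_position_majority > 0.60
  excluded <- s$worker_id[rt_rule | pos_rule]
  keep <- !(trials$worker_id %in% excluded)
  report <- data.frame(
    worker_id = excluded,
    rule_rt = rt_rule[match(excluded, s$worker_id)],
    rule_position = pos_rule[match(excluded, s$worker_id)],
    n_trials = s$n_trials[match(excluded, s$worker_id)],
    stringsAsFactors = FALSE)
  n_exc <- sum(!keep)
  attr(report, "n_excluded_trials") <- n_exc
  attr(report, "n_total_trials") <- nrow(trials)
  attr(report, "pct_excluded") <- format_pct(n_exc, nrow(trials))
  list(trials = trials[keep, , drop = FALSE], report = report)
}

#' Format an exclusion percentage
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 2).
#' @return A string like `"9.19%"`.
#' @export
format_pct <- function(numerator, denominator, digits = 2) {
  if (denominator == 0) return(NA_character_)
  paste0(formatC(100 * numerator / denominator, format = "f",
                 digits = digits), "%")
}

# quiet R CMD check notes for data.table NSE symbols
utils::globalVariables(c("rt_ms", "position", "worker_id", ".N"))
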