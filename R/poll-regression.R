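# Converting categorical survey counts and star-rating histograms into
# (f, f_e) points.

#' Construct a table of poll records
#'
#' One row per survey unit (a country-year, a rated item, ...) with counts
#' for the four ordered response categories. The categories are disjoint:
#' `c_pos` holds the moderately positive responses, `c_strong_pos` the
#' extreme ones. `n_total` is the full surveyed population and may exceed
#' the category sum when there is nonresponse.
#'
#' @param unit character or factor unit labels.
#' @param c_strong_pos,c_pos,c_neg,c_strong_neg non-negative integer
#'   counts.
#' @param n_total total surveyed per unit; defaults to the category sum.
#' @return data.frame of class `poll_table`.
#' @export
poll_table <- function(unit, c_strong_pos, c_pos, c_neg, c_strong_neg,
                       n_total = NULL) {
  cats <- cbind(c_strong_pos, c_pos, c_neg, c_strong_neg)
  if (any(cats < 0)) stop("counts must be non-negative")
  tot <- rowSums(cats)
  if (is.null(n_total)) n_total <- tot
  if (any(tot > n_total)) stop("category counts exceed n_total")
  out <- data.frame(unit = as.character(unit),
                    c_strong_pos = as.integer(c_strong_pos),
                    c_pos = as.integer(c_pos),
                    c_neg = as.integer(c_neg),
                    c_strong_neg = as.integer(c_strong_neg),
                    n_total = as.integer(n_total))
  class(out) <- c("poll_table", "data.frame")
  out
}

#' Convert poll records to (f, fe) points
#'
#' For each unit and polarity: `f = N^+ / N` with
#' `N^+ = strong-positive + positive` (mirrored for negative) and
#' `fe = N_e^+ / N` with `N_e^+` the strong count alone. The denominator
#' `N` is by default the full surveyed total including nonresponse; set
#' `include_nonresponse = FALSE` to divide by the category sum instead.
#'
#' @param records a [poll_table()] (or data.frame with its columns).
#' @param include_nonresponse divide by `n_total` (default) or by the sum
#'   of the four category counts.
#' @return data.frame with columns `unit`, `polarity`, `f`, `fe`.
#' @examples
#' tb <- poll_table("x", 200, 400, 300, 100)
#' to_ffe(tb)   # positive point (0.6, 0.2); negative point (0.4, 0.1)
#' @export
to_ffe <- function(records, include_nonresponse = TRUE) {
  r <- as.data.frame(records)
  N <- if (include_nonresponse) r$n_total
       else r$c_strong_pos + r$c_pos + r$c_neg + r$c_strong_neg
  if (any(N == 0)) stop("zero total surveyed population")
  pos <- data.frame(unit = r$unit, polarity = "positive",
                    f = (r$c_strong_pos + r$c_pos) / N,
                    fe = r$c_strong_pos / N)
  neg <- data.frame(unit = r$unit, polarity = "negative",
                    f = (r$c_strong_neg + r$c_neg) / N,
                    fe = r$c_strong_neg / N)
  rbind(pos, neg)
}

#' Star-rating opinion maps
#'
#' A star map assigns rating levels to the four opinion categories. The
#' polarity sets are inclusive (the extreme set is a subset of its
#' polarity set) and the two polarities must be disjoint; levels in
#' neither set are treated as neutral.
#'
#' @param n_levels number of star levels.
#' @param positive,extreme_positive,negative,extreme_negative integer
#'   sets of levels.
#' @return object of class `star_map`.
#' @export
star_map <- function(n_levels, positive, extreme_positive, negative,
                     extreme_negative) {
  chk <- function(s) all(s %in% seq_len(n_levels))
  if (!chk(positive) || !chk(negative)) stop("levels out of range")
  if (!all(extreme_positive %in% positive) ||
      !all(extreme_negative %in% negative))
    stop("extreme sets must be subsets of their polarity sets")
  if (length(intersect(positive, negative)) > 0)
    stop("polarity sets must be disjoint")
  structure(list(n_levels = as.integer(n_levels),
                 positive = as.integer(positive),
                 extreme_positive = as.integer(extreme_positive),
                 negative = as.integer(negative),
                 extreme_negative = as.integer(extreme_negative)),
            class = "star_map")
}

#' @rdname star_map
#' @details `star_map_imdb()` is the 10-star movie-rating convention
#'   (extreme positive: 9-10; positive: 7-10; negative: 1-4; extreme
#'   negative: 1-2). `star_map_amazon()` is the 5-star convention
#'   (extreme positive: 5; positive: 4-5; negative: 1-2; extreme
#'   negative: 1).
#' @export
star_map_imdb <- function() {
  star_map(10, positive = 7:10, extreme_positive = 9:10,
           negative = 1:4, extreme_negative = 1:2)
}

#' @rdname star_map
#' @export
star_map_amazon <- function() {
  star_map(5, positive = 4:5, extreme_positive = 5,
           negative = 1:2, extreme_negative = 1)
}

#' @rdname star_map
#' @param path JSON file with fields `n_levels`, `positive`,
#'   `extreme_positive`, `negative`, `extreme_negative`. A six-level
#'   party-orientation map (extreme-left .. right) ships in
#'   `system.file("extdata", "orientation_map.json", package = "stubborn")`.
#' @export
star_map_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  star_map(j$n_levels, j$positive, j$extreme_positive, j$negative,
           j$extreme_negative)
}

#' Convert a star-rating histogram to a poll record
#'
#' Category counts are sums over the mapped level sets, stored disjointly
#' (the moderate category is the polarity set minus its extreme subset, so
#' the four categories partition the mapped votes and
#' [to_ffe()] reconstructs the inclusive counts).
#'
#' @param histogram integer vote counts per star level (length
#'   `map$n_levels`).
#' @param map a [star_map()].
#' @param unit unit label for the record.
#' @return a one-row [poll_table()].
#' @examples
#' h <- c(10, 10, 0, 30, 50)
#' stars_to_record(h, star_map_amazon(), "book")
#' @export
stars_to_record <- function(histogram, map, unit = "item") {
  if (length(histogram) != map$n_levels)
    stop("histogram length must match the map's level count")
  if (sum(histogram) == 0) stop("empty histogram")
  poll_table(unit,
             c_strong_pos = sum(histogram[map$extreme_positive]),
             c_pos = sum(histogram[setdiff(map$positive,
                                           map$extreme_positive)]),
             c_neg = sum(histogram[setdiff(map$negative,
                                           map$extreme_negative)]),
             c_strong_neg = sum(histogram[map$extreme_negative]),
             n_total = sum(histogram))
}

#' Within-polarity shuffle null
#'
#' Destroys the extreme/moderate correlation while preserving polarity
#' totals: every positive vote is independently reassigned uniformly
#' among the positive star levels, and likewise for negative votes;
#' neutral levels are untouched.
#'
#' @param histogram integer vote counts per star level.
#' @param map a [star_map()].
#' @param seed optional seed.
#' @return shuffled histogram (same length and polarity totals).
#' @export
shuffle_null <- function(histogram, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- as.integer(histogram)
  redistribute <- function(levels) {
    tot <- sum(out[levels])
    if (tot > 0 && length(levels) > 1)
      out[levels] <<- as.integer(rmultinom(1, tot,
                                           rep(1, length(levels))))
  }
  redistribute(map$positive)
  redistribute(map$negative)
  out
}

#' Read / write the poll CSV schema
#'
#' Columns: `unit`, `c_strong_pos`, `c_pos`, `c_neg`, `c_strong_neg`,
#' `n_total`.
#'
#' @param path CSV file path.
#' @param table a [poll_table()].
#' @export
read_poll_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  poll_table(d$unit, d$c_strong_pos, d$c_pos, d$c_neg, d$c_strong_neg,
             d$n_total)
}

#' @rdname read_poll_csv
#' @export
write_poll_csv <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
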