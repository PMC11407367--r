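#' GHSI indicator code map
#'
#' The 37 Global Health Security Index indicators grouped into six
#' categories — Prevent (p11-p16), Detect (d21-d26), Respond (r31-r37),
#' Health (h41-h47), Norms (n51-n56), Risk (r61-r65). Shipped as a
#' declarative CSV (`extdata/ghsi_indicator_codes.csv`) so the
#' indicator-name matching can be edited if the public CSV's column
#' wording drifts between editions.
#'
#' @param path path to a mapping CSV with columns `category`,
#'   `category_code`, `indicator`, `code`; defaults to the shipped map.
#' @return Data frame with the 37 (category, indicator, code) rows.
#' @export
ghsi_code_map <- function(path = system.file("extdata",
                                             "ghsi_indicator_codes.csv",
                                             package = "bibeta")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  need <- c("category", "category_code", "indicator", "code")
  if (!all(need %in% names(map)))
    stop("code map must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$code)) stop("duplicate indicator codes in map")
  map
}

# Canonical form for fuzzy indicator-name matching: lower-case, collapse
# whitespace, drop punctuation.
canon_name <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Read a GHSI-style wide CSV into a country-year panel
#'
#' Expects one row per country-year with a country column, a year column
#' and one column per indicator, scores on the 0-100 scale. Indicator
#' columns are resolved against the code map's indicator names
#' case- and whitespace-insensitively; unmapped extra columns are dropped
#' with a warning. Optional `iso3`, `region`, `subregion` columns are
#' carried through as metadata.
#'
#' @param path path to the wide CSV.
#' @param code_map an indicator code map, see [ghsi_code_map()].
#' @return A long data frame of class `ghsi_panel` with columns `country`,
#'   `year`, `code`, `score` (plus any metadata columns present).
#' @export
read_ghsi_csv <- function(path, code_map = ghsi_code_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  wide <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  nm_canon <- canon_name(names(wide))
  country_col <- which(nm_canon %in% c("country", "country name"))[1L]
  year_col <- which(nm_canon == "year")[1L]
  if (is.na(country_col)) stop("no country column found")
  if (is.na(year_col)) stop("no year column found")

  # resolve indicator columns by canonical name, falling back to the code
  map_canon <- canon_name(code_map$indicator)
  idx <- match(map_canon, nm_canon)
  by_code <- match(canon_name(code_map$code), nm_canon)
  idx[is.na(idx)] <- by_code[is.na(idx)]
  if (anyNA(idx))
    stop("missing indicator column(s): ",
         paste(code_map$indicator[is.na(idx)], collapse = "; "))

  meta_cols <- which(nm_canon %in% c("iso3", "iso alpha 3", "region",
                                     "subregion"))
  extra <- setdiff(seq_along(wide), c(country_col, year_col, idx, meta_cols))
  if (length(extra) > 0L)
    warning(sprintf("dropping %d unmapped column(s): %s", length(extra),
                    paste(utils::head(names(wide)[extra], 5L),
                          collapse = ", ")),
            call. = FALSE)

  n <- nrow(wide)
  panel <- data.frame(
    country = rep(as.character(wide[[country_col]]), times = length(idx)),
    year = rep(as.integer(wide[[year_col]]), times = length(idx)),
    code = rep(code_map$code, each = n),
    score = as.numeric(unlist(wide[idx], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  for (mc in meta_cols) {
    nm <- gsub(" ", "_", nm_canon[mc])
    panel[[nm]] <- rep(as.character(wide[[mc]]), times = length(idx))
  }

  bad <- which(is.na(panel$score) | panel$score < 0 | panel$score > 100)
  if (length(bad) > 0L)
    stop(sprintf("score out of [0, 100] for country '%s', indicator '%s'",
                 panel$country[bad[1L]], panel$code[bad[1L]]))
  key <- paste(panel$country, panel$year, panel$code, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (country, year, indicator) record: ",
         gsub("\r", " / ", d))
  }
  message(sprintf("GHSI panel: %d records (%d countries x %d indicators, %d year(s))",
                  nrow(panel), length(unique(panel$country)),
                  length(unique(panel$code)),
                  length(unique(panel$year))))
  structure(panel, class = c("ghsi_panel", "data.frame"))
}

#' Build a per-year decision matrix from a GHSI panel
#'
#' Alternatives are the countries (sorted alphabetically); criteria are the
#' 37 indicator codes in category order. Every country must have all 37
#' indicators for the requested year — countries with gaps are an error,
#' not imputed.
#'
#' @param panel a `ghsi_panel` from [read_ghsi_csv()].
#' @param year the edition year to extract (e.g. 2019 or 2021).
#' @param code_map indicator code map fixing the criterion order.
#' @return A [decision_matrix()] of countries x 37 indicators.
#' @export
panel_to_decision_matrix <- function(panel, year,
                                     code_map = ghsi_code_map()) {
  sub <- panel[panel$year == year, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records for year ", year)
  countries <- sort(unique(sub$country))
  codes <- code_map$code
  m <- matrix(NA_real_, nrow = length(countries), ncol = length(codes),
              dimnames = list(countries, codes))
  m[cbind(match(sub$country, countries), match(sub$code, codes))] <- sub$score
  if (anyNA(m)) {
    gap <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("country '%s' is missing indicator '%s' for %d",
                 countries[gap[1L]], codes[gap[2L]], as.integer(year)))
  }
  decision_matrix(m)
}

#' Neutral weight table for the 37 GHSI indicators
#'
#' Category sizes 6/6/7/7/6/5 (Prevent, Detect, Respond, Health, Norms,
#' Risk) with each category's unit weight split evenly: exact fractions
#' 1/6, 1/6, 1/7, 1/7, 1/6, 1/5 per indicator. Their sum is exactly 6.
#'
#' @param code_map indicator code map, see [ghsi_code_map()].
#' @return A `neutral_weights` table (see [neutral_weights()]).
#' @export
ghsi_neutral_weights <- function(code_map = ghsi_code_map()) {
  sizes <- table(factor(code_map$category, levels = unique(code_map$category)))
  neutral_weights(stats::setNames(as.integer(sizes), names(sizes)),
                  criteria = code_map$code)
}

#' Criterion specification for a GHSI-style decision matrix
#'
#' All 37 indicators are max-direction (higher preparedness scores are
#' better), ideals follow the column-mean policy, and weights are the
#' normalized neutral weights (each summing category weight divided by the
#' total of 6), so Prevent/Detect/Norms indicators get 1/36, Respond/Health
#' 1/42 and Risk 1/30.
#'
#' @param dm a [decision_matrix()] whose criteria are the 37 GHSI codes.
#' @param code_map indicator code map.
#' @return A [criterion_spec()] aligned with `dm`.
#' @export
ghsi_criterion_spec <- function(dm, code_map = ghsi_code_map()) {
  if (!identical(colnames(dm), code_map$code))
    stop("decision matrix criteria must be the 37 GHSI indicator codes ",
         "in category order")
  w <- normalize_neutral_weights(ghsi_neutral_weights(code_map))
  criterion_spec(code_map$code, direction = "max", ideal = NA_real_,
                 weight = unname(w))
}

#' Published reference BI-beta score table (top 33 countries)
#'
#' The published country-level results of the 2019/2021 global
#' health-security scoring study for the 33 highest-ranked countries of
#' 2021: in-class score `t_ci`, index reference score `b_ri`, BI-beta
#' score and rank, per edition year, at the reporting precision of the
#' original tables (2 decimals). Useful for self-consistency checks
#' (`100 * t_ci / b_ri` must reproduce each score within the rounding of
#' the 2-decimal `t_ci`) when the full per-indicator GHSI CSV is not
#' available locally.
#'
#' @param year `2021`, `2019`, or `"both"` (wide table).
#' @return Data frame with columns `code`, `alternative`, `t_ci`, `b_ri`,
#'   `score`, `rank` (for a single year), or the full wide table.
#' @export
ghsi_reference_scores <- function(year = c("both", "2021", "2019")) {
  year <- match.arg(as.character(year), c("both", "2021", "2019"))
  tab <- utils::read.csv(system.file("extdata",
                                     "ghsi_bibeta_reference_scores.csv",
                                     package = "bibeta"),
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (year == "both") return(tab)
  cols <- paste0(c("t_ci_", "b_ri_", "score_", "rank_"), year)
  out <- tab[, c("code", "alternative", cols)]
  names(out) <- c("code", "alternative", "t_ci", "b_ri", "score", "rank")
  out
}
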