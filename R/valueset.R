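#' Construct an additive EQ-5D-3L value set
#'
#' A value set (tariff) maps a five-dimension, three-level EQ-5D-3L profile to
#' a health-state utility. The additive form supported here covers the common
#' 3L tariff structures: a full-health value, per-dimension decrements for
#' levels 2 and 3, and optional extra constants triggered once per profile
#' (an any-problem constant applied when any dimension exceeds level 1, and an
#' any-level-3 constant applied when any dimension is at level 3). Tariff
#' coefficients are user-supplied; none are shipped.
#'
#' @param full_health Utility of profile 11111.
#' @param decrements A 2 x 5 numeric matrix (rows: level 2, level 3; columns:
#'   mobility, self_care, usual_activities, pain_discomfort,
#'   anxiety_depression), or a list of five length-2 vectors. Decrements are
#'   utility losses and are subtracted as given (supply negative values to
#'   *add* utility, which no published 3L tariff does).
#' @param any_problem Constant subtracted when any dimension is above level 1.
#' @param any_level3 Constant subtracted when any dimension is at level 3.
#' @return An object of class `value_set`.
#' @examples
#' vs <- value_set(
#'   full_health = 1,
#'   decrements = rbind(
#'     level2 = c(0.1, 0, 0, 0, 0),
#'     level3 = c(0.3, 0, 0, 0.3, 0)
#'   ),
#'   any_problem = 0.05
#' )
#' score_profile("21131", vs)
#' @export
value_set <- function(full_health = 1, decrements, any_problem = 0,
                      any_level3 = 0) {
  if (is.list(decrements)) decrements <- do.call(cbind, decrements)
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(2L, 5L))) {
    abort("`decrements` must be 2 levels x 5 dimensions.",
          class = "hsuv_parse_error")
  }
  colnames(decrements) <- eq5d_dimensions()
  rownames(decrements) <- c("level2", "level3")
  structure(list(full_health = full_health, decrements = decrements,
                 any_problem = any_problem, any_level3 = any_level3),
            class = "value_set")
}

eq5d_dimensions <- function() {
  c("mobility", "self_care", "usual_activities", "pain_discomfort",
    "anxiety_depression")
}

#' Read a value set from a YAML file
#'
#' The schema is a small key-value document:
#' ```yaml
#' full_health: 1.0
#' any_problem: 0.0
#' any_level3: 0.0
#' decrements:
#'   mobility:           [0.1, 0.3]   # [level 2, level 3]
#'   self_care:          [0.0, 0.0]
#'   usual_activities:   [0.0, 0.0]
#'   pain_discomfort:    [0.0, 0.3]
#'   anxiety_depression: [0.0, 0.0]
#' ```
#' All five dimensions are required; `any_problem` / `any_level3` default to 0.
#'
#' @param path Path to the YAML file.
#' @return A [value_set()].
#' @export
read_value_set <- function(path) {
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("Could not parse value-set file: ", conditionMessage(e)),
          class = "hsuv_parse_error")
  })
  dims <- eq5d_dimensions()
  if (is.null(raw$full_health) || is.null(raw$decrements) ||
      !all(dims %in% names(raw$decrements))) {
    abort("Value-set file must supply `full_health` and all five dimensions under `decrements`.",
          class = "hsuv_parse_error")
  }
  dec <- vapply(raw$decrements[dims], function(v) {
    v <- as.numeric(v)
    if (length(v) != 2 || anyNA(v)) {
      abort("Each dimension needs numeric [level2, level3] decrements.",
            class = "hsuv_parse_error")
    }
    v
  }, numeric(2))
  value_set(full_health = as.numeric(raw$full_health), decrements = dec,
            any_problem = as.numeric(raw$any_problem %||% 0),
            any_level3 = as.numeric(raw$any_level3 %||% 0))
}

parse_profiles <- function(profile) {
  if (is.matrix(profile)) {
    lv <- profile
  } else if (is.character(profile)) {
    if (any(nchar(profile) != 5L)) {
      abort("Profiles must be 5-digit strings such as \"21131\".",
            class = "hsuv_profile_error")
    }
    lv <- t(vapply(strsplit(profile, ""),
                   function(ch) suppressWarnings(as.integer(ch)), integer(5)))
  } else if (is.numeric(profile) && length(profile) == 5L) {
    lv <- matrix(as.integer(profile), nrow = 1)
  } else {
    abort("Unrecognized profile format.", class = "hsuv_profile_error")
  }
  if (anyNA(lv) || any(lv < 1L | lv > 3L)) {
    abort("Every EQ-5D-3L level must be 1, 2 or 3.",
          class = "hsuv_profile_error")
  }
  colnames(lv) <- eq5d_dimensions()
  lv
}

#' Score EQ-5D-3L profiles with a value set
#'
#' Computes the utility of each profile as the full-health value minus the
#' applicable per-dimension decrements and extra constants.
#'
#' @param profile A character vector of 5-digit profiles ("21131"), a length-5
#'   integer vector, or an n x 5 integer matrix of levels in \{1, 2, 3\}.
#' @param vs A [value_set()].
#' @return Numeric vector of utilities.
#' @export
score_profile <- function(profile, vs) {
  stopifnot(inherits(vs, "value_set"))
  lv <- parse_profiles(profile)
  dec2 <- vs$decrements["level2", ]
  dec3 <- vs$decrements["level3", ]
  per_dim <- (lv == 2L) %*% dec2 + (lv == 3L) %*% dec3
  u <- vs$full_health - as.numeric(per_dim) -
    vs$any_problem * (rowSums(lv > 1L) > 0) -
    vs$any_level3 * (rowSums(lv == 3L) > 0)
  as.numeric(u)
}

#' Score EQ-5D-3L profiles stored in a data frame
#'
#' Data-frame-first wrapper around [score_profile()]: adds (or replaces) an
#' `hsuv` column computed from a profile column or five level columns.
#'
#' @param data A data frame.
#' @param vs A [value_set()].
#' @param profile_col Name of a character column holding 5-digit profiles. If
#'   absent, the five level columns `mobility`, `self_care`,
#'   `usual_activities`, `pain_discomfort`, `anxiety_depression` are used.
#' @return `data` as a tibble with an `hsuv` column.
#' @export
score_eq5d <- function(data, vs, profile_col = "profile") {
  data <- tibble::as_tibble(data)
  if (profile_col %in% names(data)) {
    u <- score_profile(as.character(data[[profile_col]]), vs)
  } else if (all(eq5d_dimensions() %in% names(data))) {
    lv <- as.matrix(data[eq5d_dimensions()])
    u <- score_profile(lv, vs)
  } else {
    abort("Need a `profile` column or the five EQ-5D level columns.",
          class = "hsuv_profile_error")
  }
  dplyr::mutate(data, hsuv = u)
}

#' Enumerate the attainable utility grid of a value set
#'
#' Scores all 3^5 = 243 EQ-5D-3L profiles and returns the deduplicated,
#' ascending set of attainable utilities. The first element is the minimum
#' attainable value and the last the full-health value. Used for the default
#' ALDVMM near-ceiling censoring threshold and for discretizing synthetic
#' utilities onto a realistic grid.
#'
#' @param vs A [value_set()].
#' @return Sorted numeric vector of attainable utilities (length <= 243).
#' @export
enumerate_grid <- function(vs) {
  lv <- as.matrix(expand.grid(rep(list(1:3), 5)))
  sort(unique(round(score_profile(lv, vs), 10)))
}
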