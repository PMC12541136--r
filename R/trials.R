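#' Feeding-trial tables
#'
#' A feeding-trial table holds one row per microcosm: which predator species,
#' the habitat treatment, how many prey were offered and how many were eaten
#' within the trial duration. The habitat treatment is described three ways
#' at once, mirroring the experimental design: the ordinal complexity level
#' (0-4, ordered by fractal dimension of the structure), the amount of
#' structure (0, 2 or 3 plastic-plant rings), and its presence/absence.
#' Levels 1-2 are built from 2 rings, levels 3-4 from 3 rings; level 0 has
#' none, so the three descriptors are mutually consistent and
#' `feeding_trials()` enforces that consistency.
#'
#' @param df a data.frame with columns `species`, `complexity_level`,
#'   `n_initial`, `n_eaten`; optionally `n_rings`, `structure_present`
#'   (derived from the level when absent), `duration_d` (default 1) and
#'   `block`.
#' @return the validated table, classed `feeding_trials`.
#' @export
feeding_trials <- function(df) {
  stopifnot(is.data.frame(df))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("species", "complexity_level", "n_initial", "n_eaten")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feeding_trials: missing column(s): ", paste(miss, collapse = ", "))
  if (!"duration_d" %in% names(df)) df$duration_d <- 1
  if (!"block" %in% names(df)) df$block <- NA_character_
  df$species <- as.character(df$species)
  df$complexity_level <- as.integer(df$complexity_level)
  df$n_initial <- as.integer(df$n_initial)
  df$n_eaten <- as.integer(df$n_eaten)
  df$duration_d <- as.numeric(df$duration_d)
  derived_rings <- rings_for_level(df$complexity_level)
  if (!"n_rings" %in% names(df)) df$n_rings <- derived_rings
  df$n_rings <- as.integer(df$n_rings)
  if (!"structure_present" %in% names(df)) df$structure_present <- df$n_rings > 0L
  df$structure_present <- as.logical(df$structure_present)

  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i))
      stop("feeding_trials: ", msg, " (row", if (length(i) > 1) "s", " ",
           paste(utils::head(i, 5), collapse = ", "),
           if (length(i) > 5) ", ..." else "", ")")
  }
  bad_row(is.na(df$complexity_level) | df$complexity_level < 0L |
            df$complexity_level > 4L, "complexity_level must be 0..4")
  bad_row(is.na(df$n_initial) | df$n_initial < 1L, "n_initial must be >= 1")
  bad_row(is.na(df$n_eaten) | df$n_eaten < 0L, "n_eaten must be >= 0")
  bad_row(df$n_eaten > df$n_initial, "n_eaten exceeds n_initial")
  bad_row(!is.finite(df$duration_d) | df$duration_d <= 0, "duration_d must be > 0")
  bad_row(df$n_rings != derived_rings,
          "n_rings inconsistent with complexity_level (expect 0/2/2/3/3 for levels 0..4)")
  bad_row(df$structure_present != (df$n_rings > 0L),
          "structure_present inconsistent with n_rings")
  cols <- c("species", "complexity_level", "n_rings", "structure_present",
            "n_initial", "n_eaten", "duration_d", "block")
  df <- df[, cols]
  class(df) <- c("feeding_trials", "data.frame")
  df
}

# ring count per complexity level 0..4
rings_for_level <- function(level) c(0L, 2L, 2L, 3L, 3L)[level + 1L]

#' @export
print.feeding_trials <- function(x, ...) {
  cat("Feeding trials:", nrow(x), "microcosms,",
      length(unique(x$species)), "species,",
      length(unique(x$complexity_level)), "complexity levels\n")
  NextMethod()
}
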