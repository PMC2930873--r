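#' Average seasonal weekly activity to hours per day
#'
#' Mean of summer and winter weekly recreational-activity totals, divided
#' by 7.
#'
#' @param hours_summer,hours_winter Weekly recreational hours, >= 0.
#' @return Hours per day.
#' @export
weekly_to_daily <- function(hours_summer, hours_winter) {
  if (any(hours_summer < 0, na.rm = TRUE) ||
      any(hours_winter < 0, na.rm = TRUE)) {
    stop("weekly hours must be >= 0")
  }
  (hours_summer + hours_winter) / 2 / 7
}

#' Classify the four-level physical-activity index
#'
#' Combines occupational class with daily recreational activity hours into
#' an ordinal level: 0 = inactive, 1 = moderately inactive, 2 = moderately
#' active, 3 = active.  The mapping (sedentary: 0 h -> 0, (0, 0.5) -> 1,
#' \[0.5, 1\] -> 2, >1 -> 3; standing: 0 -> 1, (0, 0.5) -> 2, >= 0.5 -> 3;
#' physical: 0 -> 2, >0 -> 3; heavy: always 3) fills the one occupational
#' cell the source classification leaves open (standing with 0.5-1 h/d)
#' monotonically.
#'
#' @param occupation Character vector in
#'   \{"sedentary", "standing", "physical", "heavy"\}.
#' @param recreation_hours_per_day Numeric vector, >= 0.
#' @return Integer vector of levels 0-3.
#' @export
classify_activity <- function(occupation, recreation_hours_per_day) {
  vocab <- c("sedentary", "standing", "physical", "heavy")
  bad <- !occupation %in% vocab
  if (any(bad)) {
    stop("unknown occupation: ", paste(unique(occupation[bad]),
                                       collapse = ", "))
  }
  h <- recreation_hours_per_day
  if (any(h < 0, na.rm = TRUE)) stop("recreational hours must be >= 0")
  if (length(h) != length(occupation)) {
    h <- rep_len(h, length(occupation))
  }
  level <- rep(NA_integer_, length(occupation))
  sed <- occupation == "sedentary"
  level[sed & h == 0] <- 0L
  level[sed & h > 0 & h < 0.5] <- 1L
  level[sed & h >= 0.5 & h <= 1] <- 2L
  level[sed & h > 1] <- 3L
  sta <- occupation == "standing"
  level[sta & h == 0] <- 1L
  level[sta & h > 0 & h < 0.5] <- 2L
  level[sta & h >= 0.5] <- 3L
  phy <- occupation == "physical"
  level[phy & h == 0] <- 2L
  level[phy & h > 0] <- 3L
  level[occupation == "heavy"] <- 3L
  level
}

#' Activity level labels
#'
#' @return Named character vector mapping level 0-3 to its label.
#' @export
activity_labels <- function() {
  c("0" = "inactive", "1" = "moderately inactive",
    "2" = "moderately active", "3" = "active")
}
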