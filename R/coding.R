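# Binary longitudinal trait coding of longevity over ages 2-15.
#
# Traditional longevity (TL): 1 while the cow is alive, 0 from the culling
# age onward. Functional longevity (FL): 1 at ages with a calving, 0 from the
# culling age onward, missing at alive ages without a recorded calving. For
# censored cows (unknown culling age) everything after the last reported
# calving is missing. The culling year itself is coded 0.

code_one <- function(history, trait) {
  ca <- history$culling_age
  calv <- history$calving_ages[[1L]]
  code <- rep(NA_integer_, length(AGES))
  if (!is.na(ca)) {                      # known (or imputed) culling age
    if (ca < 2L) stop("culling age ", ca, " below age 2 violates the ",
                      "first-calving quality-control assumptions")
    if (trait == "TL") {
      code[AGES < ca] <- 1L
      code[AGES >= ca] <- 0L
    } else {
      if (length(calv) && any(calv >= ca))
        stop("inconsistent history for cow ", history$cow,
             ": calving at or after the culling age")
      code[AGES %in% calv] <- 1L
      code[AGES >= ca] <- 0L
    }
  } else {                               # censored: truncate after last calving
    if (length(calv)) {
      last <- max(calv)
      if (trait == "TL") code[AGES <= last] <- 1L
      else code[AGES %in% calv] <- 1L
    }
  }
  data.frame(cow = history$cow, age = AGES, code = code)
}

#' Code traditional longevity for one cow
#'
#' @param history single cow history: a one-row subset of a `cow_histories`
#'   data.frame (or an equivalent list with `cow`, `culling_age`,
#'   `calving_ages`).
#' @return data.frame with 14 rows (`cow`, `age`, `code`); `code` is 1, 0 or
#'   `NA` (missing).
#' @export
code_tl <- function(history) code_one(history, "TL")

#' Code functional longevity for one cow
#' @inheritParams code_tl
#' @return data.frame with 14 rows (`cow`, `age`, `code`).
#' @export
code_fl <- function(history) code_one(history, "FL")

#' Code a trait for a whole set of cow histories
#'
#' Vectorized equivalent of [code_tl()] / [code_fl()] returning one long
#' data.frame with exactly 14 records per cow; missing codes are `NA`.
#'
#' @param histories a `cow_histories` data.frame.
#' @param trait `"TL"` or `"FL"`.
#' @return long data.frame (`cow`, `age`, `code`) of class
#'   `trajectory_records` with attribute `trait`.
#' @export
code_trajectories <- function(histories, trait = c("TL", "FL")) {
  trait <- match.arg(trait)
  n <- nrow(histories)
  ca <- histories$culling_age
  if (any(!is.na(ca) & ca < 2L))
    stop("culling age below age 2 violates the first-calving assumptions")
  agem <- matrix(AGES, n, 14L, byrow = TRUE)
  cam <- matrix(ifelse(is.na(ca), 999L, ca), n, 14L)
  calv1 <- matrix(FALSE, n, 14L)
  for (i in seq_len(n)) {
    cv <- histories$calving_ages[[i]]
    if (length(cv)) {
      if (!is.na(ca[i]) && trait == "FL" && any(cv >= ca[i]))
        stop("inconsistent history for cow ", histories$cow[i],
             ": calving at or after the culling age")
      calv1[i, cv - 1L] <- TRUE        # ages 2..15 map to columns 1..14
    }
  }
  last_calv <- vapply(histories$calving_ages,
                      function(x) if (length(x)) max(x) else NA_integer_, 0L)
  code <- matrix(NA_integer_, n, 14L)
  known <- !is.na(ca)
  if (trait == "TL") {
    code[known & agem < cam] <- 1L
  } else {
    code[known & calv1] <- 1L
  }
  code[known & agem >= cam] <- 0L
  cens <- !known
  if (trait == "TL") {
    lcm <- matrix(ifelse(is.na(last_calv), -1L, last_calv), n, 14L)
    code[cens & agem <= lcm] <- 1L
  } else {
    code[cens & calv1] <- 1L
  }
  out <- data.frame(cow = rep(histories$cow, times = 14L),
                    age = as.vector(agem), code = as.vector(code))
  out <- out[order(match(out$cow, histories$cow), out$age), ]
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  class(out) <- c("trajectory_records", "data.frame")
  out
}

#' Export trait codes in a wide, one-column-per-age layout
#'
#' Wide export in the style of BLUPF90 data files: one row per cow and one
#' column per age, with missing records written as the numeric missing-value
#' code `miss` (to be declared weight 0 / missing downstream).
#'
#' @param records `trajectory_records` from [code_trajectories()].
#' @param file path.
#' @param miss numeric code standing in for a missing record (default -999).
#' @export
write_codes_wide <- function(records, file, miss = -999L) {
  wide <- stats::reshape(as.data.frame(records), idvar = "cow",
                         timevar = "age", direction = "wide")
  wide[is.na(wide)] <- miss
  names(wide) <- sub("^code\\.", "age", names(wide))
  utils::write.table(wide, file, sep = " ", quote = FALSE, row.names = FALSE)
}
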