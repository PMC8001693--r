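# Pedigree simulation, inbreeding, and the inverse numerator relationship
# matrix assembled by Henderson's rules.

#' Simulate a multi-generation pedigree
#'
#' Founders are split over herds with both sexes present; each subsequent
#' generation is produced by random mating within herd (sire and dam both
#' taken from the previous generation), with an exact 1:1 sex ratio so the
#' number of cows (non-founder females) is predictable. Offspring inherit the
#' dam's herd. The result is topologically ordered: parents always precede
#' offspring and unknown parents are encoded as 0.
#'
#' @param config a [sim_config()] object.
#' @return a `data.frame` of class `pedigree` with columns `id`, `sire`,
#'   `dam`, `sex`, `generation`, `birth_year`, `birth_season`, `herd`,
#'   `et_flag`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_generations
  nb <- config$n_base_animals
  herds <- rep_len(seq_len(config$n_herds), nb)
  # alternate sexes within herd so each herd holds males and females
  sex0 <- ifelse(ave(herds, herds, FUN = seq_along) %% 2 == 0, "M", "F")
  if (!any(sex0 == "F") || !any(sex0 == "M"))
    stop("impossible configuration: founder population lacks one sex")

  span <- diff(config$year_range)
  step <- max(2L, span %/% (G + 1L))
  jitter_years <- function(n, base) {
    base + sample.int(min(2L, step) , n, replace = TRUE) - 1L
  }

  ped <- data.frame(
    id = seq_len(nb), sire = 0L, dam = 0L, sex = sex0, generation = 0L,
    birth_year = jitter_years(nb, config$year_range[1L]),
    birth_season = sample.int(config$seasons_per_year, nb, replace = TRUE),
    herd = herds, et_flag = 0L, stringsAsFactors = FALSE)

  n_off <- max(2L, ceiling(2 * config$n_cows_target / G))
  for (g in seq_len(G)) {
    prev <- ped[ped$generation == g - 1L, ]
    herd_off <- rep_len(seq_len(config$n_herds), n_off)
    sire <- dam <- integer(n_off)
    for (h in unique(herd_off)) {
      rows <- which(herd_off == h)
      dams_h <- prev$id[prev$sex == "F" & prev$herd == h]
      sires_h <- prev$id[prev$sex == "M" & prev$herd == h]
      if (length(dams_h) == 0L) dams_h <- prev$id[prev$sex == "F"]
      if (length(sires_h) == 0L) sires_h <- prev$id[prev$sex == "M"]
      if (length(dams_h) == 0L || length(sires_h) == 0L)
        stop("impossible configuration: no available parents of both sexes")
      dam[rows] <- sample(rep(dams_h, 2L), length(rows), replace = TRUE)
      sire[rows] <- sample(rep(sires_h, 2L), length(rows), replace = TRUE)
    }
    ids <- max(ped$id) + seq_len(n_off)
    # first half female, second half male: keeps the sex ratio exact without
    # correlating sex with the cyclic herd assignment
    sex <- rep(c("F", "M"), c(ceiling(n_off / 2), floor(n_off / 2)))
    ped <- rbind(ped, data.frame(
      id = ids, sire = sire, dam = dam, sex = sex, generation = g,
      birth_year = jitter_years(n_off, config$year_range[1L] + g * step),
      birth_season = sample.int(config$seasons_per_year, n_off, replace = TRUE),
      herd = herd_off,
      et_flag = ifelse(sex == "F",
                       stats::rbinom(n_off, 1L, config$et_proportion), 0L),
      stringsAsFactors = FALSE))
  }
  if (any(ped$birth_year > config$year_range[2L]))
    warning("generation spacing exceeds year_range; late birth years clamped")
  ped$birth_year <- pmin(ped$birth_year, config$year_range[2L])
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}

validate_pedigree <- function(ped) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) stop("pedigree needs id, sire, dam columns")
  pos <- match(ped$sire, ped$id)
  if (any(!is.na(pos) & pos >= seq_len(nrow(ped)))) stop("sire listed after offspring: pedigree not topologically ordered")
  pos <- match(ped$dam, ped$id)
  if (any(!is.na(pos) & pos >= seq_len(nrow(ped)))) stop("dam listed after offspring: pedigree not topologically ordered")
  if (any(ped$sire == ped$id | ped$dam == ped$id)) stop("animal is its own parent")
  invisible(ped)
}

# Map sire/dam ids to row positions (0 = unknown), in topological order.
parent_positions <- function(ped) {
  s <- match(ped$sire, ped$id); s[is.na(s)] <- 0L
  d <- match(ped$dam, ped$id); d[is.na(d)] <- 0L
  list(s = as.integer(s), d = as.integer(d))
}

#' Inbreeding coefficients from a pedigree
#'
#' Recursive kinship evaluation with memoization: `F_i` is the kinship between
#' the parents of `i`. Unknown parents are treated as unrelated base animals.
#'
#' @param ped a `pedigree` data.frame (topologically ordered).
#' @return numeric vector of inbreeding coefficients, one per animal.
#' @export
inbreeding_coefficients <- function(ped) {
  pp <- parent_positions(ped)
  n <- nrow(ped)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rel <- function(i, j) {
    # additive relationship a(i, j); i, j are row positions, 0 = unknown
    if (i == 0L || j == 0L) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- sprintf("%d.%d", i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      1 + 0.5 * rel(pp$s[i], pp$d[i])
    } else {
      # j is the younger animal (larger topological position)
      0.5 * (rel(i, pp$s[j]) + rel(i, pp$d[j]))
    }
    memo[[key]] <- v
    v
  }
  vapply(seq_len(n), function(i) {
    if (pp$s[i] == 0L || pp$d[i] == 0L) 0 else 0.5 * rel(pp$s[i], pp$d[i])
  }, numeric(1))
}

#' Dense additive relationship matrix (tabular method)
#'
#' Intended for small pedigrees, e.g. as an oracle when checking the sparse
#' inverse: `build_ainverse(ped) %*% relationship_matrix(ped)` is the identity.
#'
#' @param ped a `pedigree` data.frame.
#' @return dense numeric matrix `A`.
#' @export
relationship_matrix <- function(ped) {
  pp <- parent_positions(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- pp$s[i]; d <- pp$d[i]
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s > 0L) A[j, s] else 0) + (if (d > 0L) A[j, d] else 0))
      A[i, j] <- A[j, i] <- aij
    }
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles `A^-1` directly by Henderson's rules from per-animal Mendelian
#' sampling variances `d_i`. With `use_inbreeding = TRUE` the parental
#' inbreeding coefficients enter `d_i = 0.5 - 0.25 (F_s + F_d)`; otherwise
#' all `F` are taken as zero.
#'
#' @param ped a `pedigree` data.frame (topologically ordered, acyclic).
#' @param use_inbreeding account for parental inbreeding (default TRUE).
#' @return a symmetric sparse `Matrix::dsCMatrix`.
#' @export
build_ainverse <- function(ped, use_inbreeding = TRUE) {
  validate_pedigree(ped)
  pp <- parent_positions(ped)
  n <- nrow(ped)
  Fcoef <- if (use_inbreeding) inbreeding_coefficients(ped) else numeric(n)
  Fs <- ifelse(pp$s > 0L, Fcoef[pmax(pp$s, 1L)], NA_real_)
  Fd <- ifelse(pp$d > 0L, Fcoef[pmax(pp$d, 1L)], NA_real_)
  dval <- ifelse(pp$s > 0L & pp$d > 0L, 0.5 - 0.25 * (Fs + Fd),
          ifelse(pp$s > 0L, 0.75 - 0.25 * Fs,
          ifelse(pp$d > 0L, 0.75 - 0.25 * Fd, 1)))
  b <- 1 / dval

  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  idx <- seq_len(n)
  add(idx, idx, b)
  for (p in c("s", "d")) {
    k <- which(pp[[p]] > 0L)
    add(k, pp[[p]][k], -0.5 * b[k])
    add(pp[[p]][k], k, -0.5 * b[k])
    add(pp[[p]][k], pp[[p]][k], 0.25 * b[k])
  }
  both <- which(pp$s > 0L & pp$d > 0L)
  add(pp$s[both], pp$d[both], 0.25 * b[both])
  add(pp$d[both], pp$s[both], 0.25 * b[both])

  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::forceSymmetric(Ainv)
}

#' Write / read a pedigree as delimited text
#'
#' Tab-separated with a header; unknown parents are written as 0.
#' @param ped pedigree data.frame.
#' @param file path.
#' @export
write_pedigree <- function(ped, file) {
  utils::write.table(as.data.frame(ped), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(file) {
  ped <- utils::read.table(file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(ped) <- c("pedigree", "data.frame")
  validate_pedigree(ped)
  ped
}
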