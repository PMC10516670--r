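#' Resolution-limit colocalization threshold
#'
#' The smallest resolvable distance for an objective of numerical aperture
#' `NA` at emission wavelength `lambda`, by the Rayleigh criterion
#' `0.61 * lambda / NA`. Two foci of different species closer than this
#' cannot be resolved as separate signals and are scored as colocalized.
#' With the 1.4 NA objective used for this kind of imaging the thresholds
#' are 242 nm at 555 nm emission and 282 nm at 647 nm emission (integer-nm
#' reporting via `reported = TRUE`).
#'
#' @param emission_nm Emission wavelength in nm (> 0).
#' @param numerical_aperture Objective numerical aperture (> 0); default 1.4.
#' @param reported If `TRUE`, round to integer nm for reporting; the exact
#'   value is returned otherwise (and is what classification uses by
#'   default).
#' @return Threshold distance in nm.
#' @export
resolution_threshold <- function(emission_nm, numerical_aperture = 1.4,
                                 reported = FALSE) {
  if (!is.numeric(emission_nm) || any(emission_nm <= 0) ||
      !is.numeric(numerical_aperture) || any(numerical_aperture <= 0)) {
    stop("emission_nm and numerical_aperture must be positive", call. = FALSE)
  }
  thr <- 0.61 * emission_nm / numerical_aperture
  if (reported) round(thr) else thr
}

# Pairwise 3D Euclidean distances (nm) between two focus tables.
focus_nm_matrix <- function(tab) {
  cbind(tab$z_nm, tab$y_nm, tab$x_nm)
}

#' Directional nearest-neighbor colocalization classification
#'
#' For each query focus, finds the nearest focus of the reference species
#' in 3D physical coordinates and scores it colocalized iff that distance
#' is strictly under the threshold. The operation is directional:
#' classifying species A against B need not give the same counts as B
#' against A. An empty reference yields distance `Inf` and no
#' colocalization.
#'
#' @param query,reference [detection_table()]s (or focus data frames) in
#'   one physical coordinate frame.
#' @param threshold_nm Distance threshold in nm, typically from
#'   [resolution_threshold()].
#' @return A data frame `(focus_id, species, nn_dist_nm, nn_partner_id,
#'   colocalized, rel_position_pct)` with one row per query focus.
#' @export
nearest_neighbor_classify <- function(query, reference, threshold_nm) {
  q <- as.data.frame(query); r <- as.data.frame(reference)
  nq <- nrow(q)
  if (nq == 0L) {
    return(data.frame(focus_id = character(), species = character(),
                      nn_dist_nm = numeric(), nn_partner_id = character(),
                      colocalized = logical(), rel_position_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (nrow(r) == 0L) {
    nn_dist <- rep(Inf, nq)
    nn_id <- rep(NA_character_, nq)
  } else {
    qm <- focus_nm_matrix(q); rm_ <- focus_nm_matrix(r)
    d2 <- outer(rowSums(qm^2), rowSums(rm_^2), `+`) - 2 * qm %*% t(rm_)
    d2[d2 < 0] <- 0
    j <- max.col(-d2, ties.method = "first")
    nn_dist <- sqrt(d2[cbind(seq_len(nq), j)])
    nn_id <- as.character(r$focus_id[j])
  }
  rel <- if (!is.null(q$rel_position_pct)) q$rel_position_pct else NA_real_
  data.frame(focus_id = as.character(q$focus_id), species = q$species,
             nn_dist_nm = nn_dist, nn_partner_id = nn_id,
             colocalized = nn_dist < threshold_nm,
             rel_position_pct = rel,
             stringsAsFactors = FALSE)
}

#' Three-species colocalization categories
#'
#' Labels every focus of each species as solo, colocalizing with one, or
#' colocalizing with both of the other two species, by independent pairwise
#' nearest-neighbor tests. The per-pair threshold is by default the
#' resolution limit of the redder (longer-wavelength) channel of the pair,
#' since the pair's resolvability is limited by that channel.
#'
#' @param tables Named list of three [detection_table()]s; names are the
#'   species labels.
#' @param thresholds Named numeric vector/list of pairwise thresholds in
#'   nm, names `"A|B"` with the two species labels in any order; or a
#'   single number applied to all pairs.
#' @return A data frame `(species, category, n, frac)`; per-species counts
#'   sum to that species's total. The `labels` attribute carries the
#'   per-focus category assignments.
#' @export
categorize_three_species <- function(tables, thresholds) {
  stopifnot(is.list(tables), length(tables) == 3L, !is.null(names(tables)))
  sp <- names(tables)
  pair_thr <- function(a, b) {
    if (length(thresholds) == 1L && is.null(names(thresholds))) {
      return(as.numeric(thresholds))
    }
    key1 <- paste(a, b, sep = "|"); key2 <- paste(b, a, sep = "|")
    v <- thresholds[[key1]]
    if (is.null(v)) v <- thresholds[[key2]]
    if (is.null(v)) stop("no threshold for pair ", key1, call. = FALSE)
    as.numeric(v)
  }
  labels <- list()
  rows <- list()
  for (a in sp) {
    others <- setdiff(sp, a)
    with1 <- nearest_neighbor_classify(tables[[a]], tables[[others[1L]]],
                                       pair_thr(a, others[1L]))$colocalized
    with2 <- nearest_neighbor_classify(tables[[a]], tables[[others[2L]]],
                                       pair_thr(a, others[2L]))$colocalized
    cat_lab <- ifelse(with1 & with2,
                      paste0(a, "+", others[1L], "+", others[2L]),
               ifelse(with1, paste0(a, "+", others[1L]),
               ifelse(with2, paste0(a, "+", others[2L]), "solo")))
    total <- nrow(as.data.frame(tables[[a]]))
    cats <- c("solo", paste0(a, "+", others[1L]), paste0(a, "+", others[2L]),
              paste0(a, "+", others[1L], "+", others[2L]))
    n <- vapply(cats, function(cc) sum(cat_lab == cc), integer(1))
    rows[[a]] <- data.frame(species = a, category = cats, n = n,
                            frac = if (total > 0) n / total else NA_real_,
                            stringsAsFactors = FALSE)
    labels[[a]] <- data.frame(
      focus_id = as.character(as.data.frame(tables[[a]])$focus_id),
      species = a, category = cat_lab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "labels") <- do.call(rbind, c(labels, make.row.names = FALSE))
  out
}

#' Binomial confidence interval for a proportion
#'
#' Wilson score interval by default (well-behaved at extreme fractions);
#' Clopper-Pearson available as an alternative.
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @param conf_level Confidence level; default 0.95.
#' @return Numeric `(lower, upper)` on the proportion scale.
#' @export
proportion_ci <- function(k, n, method = c("wilson", "clopper-pearson"),
                          conf_level = 0.95) {
  method <- match.arg(method)
  if (n == 0L) return(c(lower = NA_real_, upper = NA_real_))
  ci <- if (method == "wilson") {
    # the chi-squared small-count warning concerns the test statistic,
    # not the score interval used here
    suppressWarnings(
      stats::prop.test(k, n, correct = FALSE,
                       conf.level = conf_level)$conf.int)
  } else {
    stats::binom.test(k, n, conf.level = conf_level)$conf.int
  }
  c(lower = ci[1L], upper = ci[2L])
}

#' Colocalization fractions with confidence intervals
#'
#' Summarises one classification run: the colocalized fraction (and
#' percentage), its 95% confidence interval, and -- when relative gonad
#' positions are attached -- the median relative position of colocalized
#' and non-colocalized foci, which orders focus categories along the
#' spatial "time course" of the gonad.
#'
#' @param records Output of [nearest_neighbor_classify()].
#' @param ci_method Passed to [proportion_ci()].
#' @return A one-row data frame `(n_total, n_coloc, fraction, percent,
#'   ci_lower, ci_upper, median_pos_coloc, median_pos_solo)`. With zero
#'   records, the fraction is `NA` and counts are 0.
#' @export
coloc_report <- function(records, ci_method = "wilson") {
  n <- nrow(records)
  k <- sum(records$colocalized)
  if (n == 0L) {
    return(data.frame(n_total = 0L, n_coloc = 0L, fraction = NA_real_,
                      percent = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, median_pos_coloc = NA_real_,
                      median_pos_solo = NA_real_))
  }
  ci <- proportion_ci(k, n, method = ci_method)
  med <- function(x) if (length(x) && !all(is.na(x))) {
    stats::median(x, na.rm = TRUE)
  } else NA_real_
  data.frame(
    n_total = n, n_coloc = k, fraction = k / n, percent = 100 * k / n,
    ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
    median_pos_coloc = med(records$rel_position_pct[records$colocalized]),
    median_pos_solo = med(records$rel_position_pct[!records$colocalized])
  )
}
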