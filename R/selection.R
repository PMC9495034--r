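# Jacobs selection indices: use-vs-availability preference per environmental
# factor category, computed per week for location fixes and for droppings,
# with across-category and fixes-vs-droppings comparisons.

#' Jacobs selection index
#'
#' `JSI = (r - p) / (r + p - 2 r p)`, where `r` is the fraction of use
#' (location fixes or feces) in an area unit and `p` the fraction of the
#' paddock that unit represents. Ranges from -1 (complete avoidance) to +1
#' (complete selection). Equal fractions (including the removable 0/0 case) return
#' 0 by continuity.
#'
#' @param r,p Fractions in `[0, 1]`, vectorized.
#' @return JSI values in `[-1, 1]`.
#' @export
jacobs_index <- function(r, p) {
  if (any(r < 0 | r > 1 | p < 0 | p > 1, na.rm = TRUE))
    stop("r and p must be fractions in [0, 1]")
  out <- ifelse(r == p, 0, (r - p) / (r + p - 2 * r * p))
  # the ratio can overshoot the algebraic bounds by an ulp at r or p = 1
  pmin(pmax(out, -1), 1)
}

#' Weekly selection records for one factor
#'
#' Assigns use points (fixes or dung events) to the categories of a
#' categorical raster by cell membership, computes the weekly use fractions
#' `r`, the availability fractions `p` from the raster's category areas, and
#' the Jacobs index per category and week. Weeks with zero total points are
#' skipped (with a message).
#'
#' @param points Data frame with `x`, `y`, `week`.
#' @param cat_raster Categorical [raster_layer()] (e.g. from [bin_raster()]).
#' @param factor Factor name recorded in the output.
#' @param subject `"fixes"` or `"droppings"`.
#' @return Data frame `factor`, `category`, `week`, `subject`, `r`, `p`,
#'   `jsi`.
#' @export
weekly_selection <- function(points, cat_raster, factor = "factor",
                             subject = c("fixes", "droppings")) {
  subject <- match.arg(subject)
  p_avail <- category_fractions(cat_raster)
  cats <- cat_raster$categories
  lab <- values_at(cat_raster, points$x, points$y, label = TRUE)
  ok <- !is.na(lab)
  pts <- data.frame(week = points$week[ok], category = lab[ok])
  out <- list()
  for (w in sort(unique(pts$week))) {
    sel <- pts$category[pts$week == w]
    if (!length(sel)) { message("week ", w, ": no points, skipped"); next }
    n <- table(factor(sel, levels = cats))
    r <- as.numeric(n) / sum(n)
    out[[length(out) + 1]] <- data.frame(
      factor = factor, category = cats, week = w, subject = subject,
      r = r, p = as.numeric(p_avail[cats]),
      jsi = jacobs_index(r, as.numeric(p_avail[cats])))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weekly selection for all standard factors
#'
#' Bins the slope, canopy and distance-to-water layers with the standard
#' category sets ([factor_bins()]), reuses the categorical insolation layer,
#' and computes [weekly_selection()] for fixes and dung events.
#'
#' @param fix_points,dung_points Data frames with `x`, `y`, `week`.
#' @param layers Named layer list with `slope`, `insolation`, `canopy`,
#'   `dist_water` (as from [gen_paddock()]).
#' @return Combined selection record data frame.
#' @export
selection_by_factors <- function(fix_points, dung_points, layers) {
  cat_layers <- list(
    slope = bin_raster(layers$slope, factor_bins("slope")),
    insolation = layers$insolation,
    canopy = bin_raster(layers$canopy, factor_bins("canopy")),
    distance_to_water = bin_raster(layers$dist_water,
                                   factor_bins("distance_to_water")))
  out <- list()
  for (nm in names(cat_layers)) {
    out[[length(out) + 1]] <-
      weekly_selection(fix_points, cat_layers[[nm]], nm, "fixes")
    out[[length(out) + 1]] <-
      weekly_selection(dung_points, cat_layers[[nm]], nm, "droppings")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# compact letter display from a pairwise non-significance matrix: letters are
# maximal cliques of the "not significantly different" graph, ordered by
# group mean (brute-force enumeration; category counts are small)
cld_letters <- function(nonsig, means) {
  k <- nrow(nonsig)
  if (k == 1) return(stats::setNames("a", rownames(nonsig)))
  subsets <- lapply(seq_len(2^k - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s)
    all(nonsig[s, s, drop = FALSE]), logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i)
    !any(vapply(cliques, function(o)
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o),
      logical(1))), logical(1))]
  ord <- order(vapply(maximal, function(s) mean(means[s]), 0))
  lets <- rep("", k)
  for (j in seq_along(ord)) {
    s <- maximal[[ord[j]]]
    lets[s] <- paste0(lets[s], letters[j])
  }
  stats::setNames(lets, rownames(nonsig))
}

#' Summarize weekly selection indices
#'
#' Per factor, subject and category: mean JSI over weeks with SD;
#' across-category comparison letters from a Kruskal-Wallis omnibus test
#' followed by pairwise Wilcoxon rank-sum tests (Holm-adjusted, alpha 0.05);
#' and fixes-vs-droppings significance stars per category from a paired
#' Wilcoxon signed-rank test on matching weeks (`*`, `**`, `***` for p <
#' 0.05 / 0.01 / 0.001).
#'
#' @param records Weekly selection records ([weekly_selection()] /
#'   [selection_by_factors()]).
#' @param alpha Significance level for the letter display.
#' @return Data frame `factor`, `subject`, `category`, `mean_jsi`, `sd_jsi`,
#'   `n_weeks`, `letters`, `stars` (stars only where both subjects present).
#' @export
summarize_selection <- function(records, alpha = 0.05) {
  out <- list()
  for (fac in unique(records$factor)) {
    rf <- records[records$factor == fac, ]
    for (sub in unique(rf$subject)) {
      rs <- rf[rf$subject == sub, ]
      cats <- unique(rs$category)
      mean_jsi <- tapply(rs$jsi, factor(rs$category, levels = cats), mean)
      sd_jsi <- tapply(rs$jsi, factor(rs$category, levels = cats), stats::sd)
      n_weeks <- tapply(rs$jsi, factor(rs$category, levels = cats), length)
      lets <- rep(NA_character_, length(cats))
      if (length(cats) > 1 && min(n_weeks) >= 2) {
        if (all(tapply(rs$jsi, rs$category, function(v)
          stats::var(v) == 0)) &&
            length(unique(round(rs$jsi, 12))) == 1) {
          lets <- rep("a", length(cats))   # identical everywhere
        } else {
          kw <- suppressWarnings(
            stats::kruskal.test(rs$jsi, factor(rs$category)))
          nonsig <- matrix(TRUE, length(cats), length(cats),
                           dimnames = list(cats, cats))
          if (is.finite(kw$p.value) && kw$p.value < alpha) {
            pw <- suppressWarnings(stats::pairwise.wilcox.test(
              rs$jsi, factor(rs$category, levels = cats),
              p.adjust.method = "holm", exact = FALSE))
            pm <- pw$p.value
            for (i in rownames(pm)) for (j in colnames(pm)) {
              if (!is.na(pm[i, j]) && pm[i, j] < alpha) {
                nonsig[i, j] <- FALSE; nonsig[j, i] <- FALSE
              }
            }
          }
          lets <- cld_letters(nonsig, mean_jsi[cats])[cats]
        }
      }
      out[[length(out) + 1]] <- data.frame(
        factor = fac, subject = sub, category = cats,
        mean_jsi = as.numeric(mean_jsi[cats]),
        sd_jsi = as.numeric(sd_jsi[cats]),
        n_weeks = as.integer(n_weeks[cats]), letters = lets,
        stars = NA_character_)
    }
    # fixes-vs-droppings stars per category on matching weeks
    if (all(c("fixes", "droppings") %in% rf$subject)) {
      for (cat in unique(rf$category)) {
        a <- rf[rf$subject == "fixes" & rf$category == cat, ]
        b <- rf[rf$subject == "droppings" & rf$category == cat, ]
        wk <- intersect(a$week, b$week)
        if (length(wk) < 2) next
        av <- a$jsi[match(wk, a$week)]; bv <- b$jsi[match(wk, b$week)]
        if (all(av == bv)) { st <- "" } else {
          p <- suppressWarnings(
            stats::wilcox.test(av, bv, paired = TRUE, exact = FALSE))$p.value
          st <- if (!is.finite(p)) "" else if (p < 0.001) "***"
                else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
        }
        for (k in seq_along(out)) {
          if (out[[k]]$factor[1] == fac)
            out[[k]]$stars[out[[k]]$category == cat] <- st
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
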