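#' Pearson correlation with analytic standard error
#'
#' Record-level Pearson correlation on pairwise-complete observations with
#' SE = sqrt((1 - r^2) / (n - 2)).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with \code{r}, \code{se}, \code{n}. \code{r} is \code{NA}
#'   when either vector is constant or fewer than 3 pairs remain.
#' @examples
#' correlate(1:10, 2 * (1:10))  # r = 1, se = 0
#' @export
correlate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, se = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  list(r = r, se = sqrt((1 - r^2) / (n - 2)), n = n)
}

#' Correlation table across trait columns
#'
#' All pairwise record-level Pearson correlations among the given columns,
#' in long format (one row per unordered pair).
#'
#' @param traits Data frame of trait columns.
#' @param columns Columns to correlate (default: all numeric).
#' @return Data frame: trait_a, trait_b, r, se, n.
#' @export
correlation_matrix <- function(traits, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(traits)[vapply(traits, is.numeric, TRUE)]
  }
  pairs <- utils::combn(columns, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    cc <- correlate(traits[[pairs[1, k]]], traits[[pairs[2, k]]])
    data.frame(trait_a = pairs[1, k], trait_b = pairs[2, k],
               r = cc$r, se = cc$se, n = cc$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# compact letter display from a logical "significantly different" matrix
# (insert-and-absorb): animals of the same letter are not distinguishable
cld_letters <- function(signif_mat) {
  g <- rownames(signif_mat)
  groups <- list(g)
  for (a in g) for (b in g) {
    if (a < b && signif_mat[a, b]) {
      groups_new <- list()
      for (grp in groups) {
        if (all(c(a, b) %in% grp)) {
          groups_new <- c(groups_new, list(setdiff(grp, a)),
                          list(setdiff(grp, b)))
        } else groups_new <- c(groups_new, list(grp))
      }
      # absorb subsets
      keep <- rep(TRUE, length(groups_new))
      for (i in seq_along(groups_new)) for (j in seq_along(groups_new)) {
        if (i != j && keep[j] &&
            all(groups_new[[i]] %in% groups_new[[j]]) &&
            (length(groups_new[[i]]) < length(groups_new[[j]]) || i > j)) {
          keep[i] <- FALSE
        }
      }
      groups <- unique(groups_new[keep])
    }
  }
  lets <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(groups)) {
    for (m in groups[[k]]) lets[m] <- paste0(lets[m], letters[k])
  }
  lets
}

#' Top-quartile selection comparison across methane metrics
#'
#' Identifies, for each metric, the most efficient 25\% of animals: only
#' animals with complete data for all metrics enter; each animal is
#' represented by its most efficient (lowest) record value per metric;
#' animals are ranked ascending and the top \code{round(0.25 n)} selected
#' (ties at the boundary broken by ascending animal id). Mean and SD of the
#' accompanying traits (intake, methane, weight, cohort-specific traits)
#' are computed over the selected animals' ranking records, and groups are
#' compared pairwise by Welch t tests with Holm adjustment, annotated with
#' significance letters at \code{alpha}.
#'
#' @param metric_values Data frame with \code{record_id}, \code{animal_id}
#'   and one column per metric (e.g. ch4, mi_mbw, my, RMT_MBW+DMI).
#' @param metrics Metric column names to rank on.
#' @param group_traits Data frame keyed by \code{record_id} with the traits
#'   to average over the selected groups (e.g. dmi, ch4, body_weight).
#' @param quantile Selected fraction (default 0.25).
#' @param alpha Significance level for the letters (default 0.05).
#' @return Object of class \code{ranking_report}: \code{selected} (metric,
#'   animal_id, record_id, metric value), \code{group_means} (metric x
#'   trait mean/sd with letters), \code{pairwise} (Holm-adjusted Welch
#'   p-values) and \code{n_complete}.
#' @export
rank_top_quartile <- function(metric_values, metrics, group_traits = NULL,
                              quantile = 0.25, alpha = 0.05) {
  miss <- setdiff(metrics, names(metric_values))
  if (length(miss)) stop("metrics not found: ", paste(miss, collapse = ", "))
  # complete-case animals: at least one record with every metric present
  per_animal <- split(metric_values, metric_values$animal_id)
  complete_animal <- vapply(per_animal, function(d) {
    all(vapply(metrics, function(mcol) any(!is.na(d[[mcol]])), TRUE))
  }, TRUE)
  animals <- sort(names(per_animal)[complete_animal])
  n_complete <- length(animals)
  if (n_complete < 8L) stop("need at least 8 complete-case animals")
  n_sel <- round_half_up(quantile * n_complete)

  selected <- list()
  for (mcol in metrics) {
    best_val <- numeric(n_complete)
    best_rec <- character(n_complete)
    for (i in seq_along(animals)) {
      d <- per_animal[[animals[i]]]
      v <- d[[mcol]]
      j <- which.min(v)               # lowest record value = most efficient
      best_val[i] <- v[j]
      best_rec[i] <- d$record_id[j]
    }
    ord <- order(best_val, animals)   # boundary ties: ascending animal id
    take <- ord[seq_len(n_sel)]
    selected[[mcol]] <- data.frame(metric = mcol, animal_id = animals[take],
                                   record_id = best_rec[take],
                                   value = best_val[take],
                                   stringsAsFactors = FALSE)
  }
  selected <- do.call(rbind, selected)
  rownames(selected) <- NULL

  group_means <- NULL
  pairwise <- NULL
  if (!is.null(group_traits)) {
    trait_cols <- setdiff(names(group_traits)[vapply(group_traits,
                                                     is.numeric, TRUE)],
                          c("record_id", "animal_id"))
    gm <- list()
    pw <- list()
    for (tc in trait_cols) {
      vals <- lapply(metrics, function(mcol) {
        sel <- selected[selected$metric == mcol, ]
        v <- group_traits[[tc]][match(sel$record_id, group_traits$record_id)]
        v[!is.na(v)]
      })
      names(vals) <- metrics
      p <- matrix(NA_real_, length(metrics), length(metrics),
                  dimnames = list(metrics, metrics))
      for (a in seq_along(metrics)) for (b in seq_along(metrics)) {
        if (a < b && length(vals[[a]]) > 1L && length(vals[[b]]) > 1L &&
            (stats::sd(vals[[a]]) > 0 || stats::sd(vals[[b]]) > 0)) {
          p[a, b] <- stats::t.test(vals[[a]], vals[[b]])$p.value
        }
      }
      ptab <- p[upper.tri(p)]
      adj <- stats::p.adjust(ptab, method = "holm")
      p_adj <- p
      p_adj[upper.tri(p_adj)] <- adj
      sig <- !is.na(p_adj) & p_adj < alpha
      sig <- sig | t(sig)
      lets <- cld_letters(sig)
      gm[[tc]] <- data.frame(
        metric = metrics, trait = tc,
        mean = vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 1),
        sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 1),
        n = vapply(vals, length, 1L),
        letters = lets[metrics], stringsAsFactors = FALSE)
      idx <- which(upper.tri(p), arr.ind = TRUE)
      pw[[tc]] <- data.frame(trait = tc, metric_a = metrics[idx[, 1]],
                             metric_b = metrics[idx[, 2]],
                             p_welch = ptab, p_holm = adj,
                             stringsAsFactors = FALSE)
    }
    group_means <- do.call(rbind, gm)
    rownames(group_means) <- NULL
    pairwise <- do.call(rbind, pw)
    rownames(pairwise) <- NULL
  }

  structure(list(selected = selected, group_means = group_means,
                 pairwise = pairwise, n_complete = n_complete,
                 n_selected = n_sel),
            class = "ranking_report")
}

#' @export
print.ranking_report <- function(x, ...) {
  cat(sprintf("Top-quartile ranking: %d complete-case animals, %d selected per metric\n",
              x$n_complete, x$n_selected))
  if (!is.null(x$group_means)) print(x$group_means, digits = 4)
  invisible(x)
}

# round() half-away-from-zero (base R rounds half to even)
round_half_up <- function(x) trunc(x + sign(x) * 0.5)
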