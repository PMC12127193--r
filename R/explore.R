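# Exploratory analytics over the selected biomarker panel: z-scored
# hierarchical clustering (Canberra distance, complete linkage), standardized
# PCA with a fixed sign convention, volcano statistics (log2 fold change +
# Student t), and a preranked gene-set enrichment analysis with
# permutation-based significance.

# z-score per biomarker (column); zero-variance columns excluded with warning
.zscore_cols <- function(matrix) {
  .assert(is.matrix(matrix), "a matrix is required")
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance biomarker(s) from z-scoring: ",
            paste(colnames(matrix)[sds == 0], collapse = ", "))
    matrix <- matrix[, sds > 0, drop = FALSE]
  }
  scale(matrix)
}

#' Hierarchical clustering of patients and biomarkers
#'
#' Biomarker levels are z-score standardized per biomarker, then patients
#' (rows) and biomarkers (columns) are clustered agglomeratively with the
#' Canberra distance and complete linkage. Clustering is deterministic given
#' the input ordering ([stats::hclust()] resolves distance ties by merge
#' index).
#'
#' @param matrix patients x biomarkers abundance matrix.
#' @param metric distance metric for [stats::dist()] (default
#'   `"canberra"`).
#' @param linkage agglomeration method (default `"complete"`).
#' @return list with `rows` and `cols` ([stats::hclust] trees), `row_order`,
#'   `col_order`, and the standardized matrix `z`.
#' @export
hcluster <- function(matrix, metric = "canberra", linkage = "complete") {
  .assert(nrow(matrix) >= 2, "at least two rows are required")
  z <- .zscore_cols(matrix)
  hr <- stats::hclust(stats::dist(z, method = metric), method = linkage)
  hc <- stats::hclust(stats::dist(t(z), method = metric), method = linkage)
  list(rows = hr, cols = hc, row_order = hr$order, col_order = hc$order,
       z = z)
}

#' Standardized principal component analysis
#'
#' PCA on centered, unit-variance biomarker columns. Constant columns are
#' dropped with a warning. Component signs follow the
#' largest-loading-positive convention (each component is flipped if its
#' largest-magnitude loading is negative), so results are reproducible
#' across platforms.
#'
#' @param matrix patients x biomarkers matrix (>= 2 rows and columns).
#' @return list with `scores`, `loadings` and `explained_variance`
#'   (fractions summing to 1).
#' @export
pca_biomarkers <- function(matrix) {
  .assert(nrow(matrix) >= 2 && ncol(matrix) >= 2,
          "at least 2 rows and 2 columns are required")
  sds <- apply(matrix, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(matrix)[sds == 0], collapse = ", "))
    matrix <- matrix[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(matrix, center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  list(scores = p$x, loadings = p$rotation,
       explained_variance = p$sdev^2 / sum(p$sdev^2))
}

#' Volcano statistics: fold change and Student t per biomarker
#'
#' For each biomarker, the log2 ratio of the mean level in responders over
#' the mean level in non-responders, and a two-sided pooled-variance
#' (Student) t-test p-value. A non-positive group mean leaves the fold
#' change missing for that biomarker.
#'
#' @param matrix patients x biomarkers abundance matrix.
#' @param responder_flags logical labels aligned with the rows; both classes
#'   required.
#' @return data.frame with `protein_id`, `log2_fc`, `p_value`.
#' @export
volcano <- function(matrix, responder_flags) {
  y <- as.logical(responder_flags)
  .assert(any(y) && any(!y), "both classes must be present")
  .assert(nrow(matrix) == length(y), "labels must align with rows")
  res <- lapply(colnames(matrix), function(id) {
    x1 <- matrix[y, id]; x0 <- matrix[!y, id]
    m1 <- mean(x1); m0 <- mean(x0)
    fc <- if (m1 > 0 && m0 > 0) log2(m1 / m0) else NA_real_
    p <- tryCatch(stats::t.test(x1, x0, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    data.frame(protein_id = id, log2_fc = fc, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (anyNA(out$log2_fc))
    warning("fold change undefined (non-positive group mean) for ",
            sum(is.na(out$log2_fc)), " biomarker(s)")
  out
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT: set name, description, then member ids. Lines with
#' fewer than three fields are skipped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character member vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    warning(sum(short), " malformed GMT line(s) skipped")
    parts <- parts[!short]
  }
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[[`, character(1), 1))
}

# Weighted Kolmogorov-Smirnov-style running sum over an already-ordered
# score vector. `in_set` flags the member positions. Returns the signed
# extremum (largest absolute deviation) and its position.
.gsea_running <- function(ordered_scores, in_set, weight = 1) {
  N <- length(ordered_scores)
  nh <- sum(in_set)
  w <- abs(ordered_scores)^weight
  nr <- sum(w[in_set])
  inc <- numeric(N)
  inc[in_set] <- if (nr > 0) w[in_set] / nr else 1 / nh
  inc[!in_set] <- -1 / (N - nh)
  rs <- cumsum(inc)
  # ties at the extremum: take the attainment that maximizes the leading
  # edge (last for positive ES, first for negative), so sign-flip symmetry
  # mirrors the edge
  at_max <- which(abs(rs) >= max(abs(rs)) - 1e-12)
  i <- if (rs[at_max[1]] >= 0) max(at_max) else min(at_max)
  list(es = unname(rs[i]), idx = i, running = rs)
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted (exponent 1) running-sum enrichment: ids are ranked by
#' score (descending, typically log2 fold change), the running sum gains
#' `|score|/NR` at members and loses `1/(N - Nh)` at non-members, and the
#' enrichment score (ES) is the signed extremum. Significance comes from
#' gene-set membership permutation (`n_perm` random same-size sets): the
#' normalized ES (NES) divides ES by the mean |null ES| of the same sign,
#' the permutation p is one-sided within sign (with add-one smoothing), and
#' the FDR q compares each NES against the pooled null and observed NES
#' distributions of the same sign. The leading edge contains the members at
#' or before (positive ES) / at or after (negative ES) the extremum.
#'
#' @param scores named numeric vector (names = ids, values = ranking
#'   scores); sorted internally in decreasing order.
#' @param gene_sets named list of member id vectors; sets that do not
#'   intersect the ranked universe are skipped with a warning.
#' @param n_perm number of membership permutations (default 1000).
#' @param seed integer seed for the permutations.
#' @param weight running-sum weight exponent (default 1; 0 gives the
#'   unweighted classic statistic).
#' @return data.frame with `set_name`, `size`, `es`, `nes`, `p_perm`,
#'   `fdr_q` and a list-column `leading_edge`.
#' @export
#' @examples
#' sc <- c(g1 = 3, g2 = 2, g3 = 1, g4 = -1, g5 = -2, g6 = -3)
#' gsea_preranked(sc, list(top = c("g1", "g3")), n_perm = 100, seed = 1)
gsea_preranked <- function(scores, gene_sets, n_perm = 1000, seed = 1,
                           weight = 1) {
  .assert(!is.null(names(scores)) && all(nzchar(names(scores))),
          "scores must be named by id")
  .assert(is.list(gene_sets) && !is.null(names(gene_sets)),
          "gene_sets must be a named list")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  ids <- names(s)
  N <- length(s)

  keep <- vapply(gene_sets, function(g) sum(ids %in% g) >= 1 &&
                   sum(ids %in% g) < N, logical(1))
  if (any(!keep))
    warning("skipping set(s) with empty (or full) overlap: ",
            paste(names(gene_sets)[!keep], collapse = ", "))
  gene_sets <- gene_sets[keep]
  .assert(length(gene_sets) >= 1, "no gene set overlaps the ranked universe")

  obs <- lapply(gene_sets, function(g) {
    in_set <- ids %in% g
    r <- .gsea_running(s, in_set, weight)
    le <- if (r$es >= 0) ids[seq_len(r$idx)][in_set[seq_len(r$idx)]]
          else ids[r$idx:N][in_set[r$idx:N]]
    list(es = r$es, size = sum(in_set), leading_edge = le)
  })

  sizes <- sort(unique(vapply(obs, `[[`, numeric(1), "size")))
  null_by_size <- with_seed(seed, {
    out <- lapply(sizes, function(nh) {
      vapply(seq_len(n_perm), function(b) {
        in_set <- rep(FALSE, N)
        in_set[sample.int(N, nh)] <- TRUE
        .gsea_running(s, in_set, weight)$es
      }, numeric(1))
    })
    stats::setNames(out, as.character(sizes))
  })

  norm1 <- function(es, null) {
    same <- null[sign(null) == sign(es) & null != 0]
    if (!length(same)) return(c(nes = NA_real_, p = NA_real_))
    nes <- es / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    c(nes = nes, p = p)
  }
  rows <- lapply(names(obs), function(nm) {
    o <- obs[[nm]]
    null <- null_by_size[[as.character(o$size)]]
    np <- norm1(o$es, null)
    data.frame(set_name = nm, size = o$size, es = o$es, nes = np["nes"],
               p_perm = np["p"], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL

  # normalized null pool for the FDR: every null ES normalized by the mean
  # |null ES| of its own sign and size
  null_nes <- unlist(lapply(names(null_by_size), function(k) {
    null <- null_by_size[[k]]
    pos <- null[null > 0]; neg <- null[null < 0]
    c(if (length(pos)) pos / mean(pos),
      if (length(neg)) neg / mean(abs(neg)))
  }), use.names = FALSE)
  res$fdr_q <- vapply(seq_len(nrow(res)), function(i) {
    nes <- res$nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num_pool <- null_nes[null_nes >= 0]; obs_pool <- res$nes[res$nes >= 0]
      num <- mean(num_pool >= nes); den <- mean(obs_pool >= nes)
    } else {
      num_pool <- null_nes[null_nes < 0]; obs_pool <- res$nes[res$nes < 0]
      num <- mean(num_pool <= nes); den <- mean(obs_pool <= nes)
    }
    min(1, num / max(den, 1e-12))
  }, numeric(1))
  res$leading_edge <- I(lapply(names(obs), function(nm) obs[[nm]]$leading_edge))
  res
}
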