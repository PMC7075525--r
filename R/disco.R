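# DisCo: distance-constraint scoring. Template structures homologous to
# the target are aligned to the target sequence; every template Calpha pair
# below 15 A yields a Gaussian constraint g_ijk(d) = exp(-0.5 (d - mu)^2).
# Templates are clustered by pairwise sequence similarity; per cluster the
# constraints are averaged (h_ijc) and clusters are combined with softmax
# weights exp(gamma * SS_c) normalized over the clusters covering the pair.
# The per-residue DisCo score averages s_ij over all partners within 15 A.

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Normalized per-column similarity of two aligned residues: BLOSUM62 score
# affinely rescaled so that the matrix minimum maps to 0 and the first
# residue's self-score maps to 1.
.column_similarity <- function(a, b) {
  B <- .blosum62()
  a[!(a %in% rownames(B))] <- "X"
  b[!(b %in% rownames(B))] <- "X"
  bmin <- min(B)
  raw <- B[cbind(a, b)]
  self <- B[cbind(a, a)]
  pmax(0, pmin(1, (raw - bmin) / (self - bmin)))
}

# mean normalized similarity and identity over aligned (non-gap) columns
.aln_stats <- function(target_res, template_res) {
  if (length(target_res) == 0) return(c(sim = 0, id = 0))
  c(sim = mean(.column_similarity(target_res, template_res)),
    id = mean(target_res == template_res))
}

#' Read an A3M/FASTA alignment
#'
#' @param path alignment file; the first record is the query/master.
#' @return list with `ids` and `seqs` (case preserved).
#' @export
read_a3m <- function(path) {
  lines <- readLines(path, warn = FALSE)
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no alignment records in ", path)
  ids <- sub("^>\\s*(\\S+).*", "\\1", lines[heads])
  bounds <- c(heads, length(lines) + 1)
  seqs <- vapply(seq_along(heads), function(k) {
    gsub("\\s", "", paste(lines[(bounds[k] + 1):(bounds[k + 1] - 1)],
                          collapse = ""))
  }, "")
  list(ids = ids, seqs = seqs)
}

# target->template index mapping from one A3M row (master assumed
# ungapped uppercase; lowercase in the template = insertion, consumed
# without advancing the master)
.a3m_mapping <- function(template_row, target_length) {
  chars <- strsplit(template_row, "")[[1]]
  map <- integer(0)
  qpos <- 0L; tpos <- 0L
  taa <- character(0)
  for (ch in chars) {
    if (ch %in% c("-", ".")) {
      if (ch == "-") qpos <- qpos + 1L
      next
    }
    if (ch == tolower(ch) && ch != toupper(ch)) {   # lowercase insertion
      tpos <- tpos + 1L
      next
    }
    qpos <- qpos + 1L; tpos <- tpos + 1L
    if (qpos <= target_length) {
      map[as.character(qpos)] <- tpos
      taa[as.character(qpos)] <- ch
    }
  }
  list(map = map, taa = taa)
}

#' Load aligned templates
#'
#' Parses an A3M alignment whose first record is the target and attaches
#' C-alpha coordinates from per-template PDB files (`<template_id>.pdb`
#' under `template_dir`). Sequence similarity is the BLOSUM62-normalized
#' per-aligned-column mean in [0,1]; identity the fraction of identical
#' aligned positions. Mapped template positions lacking a C-alpha are
#' dropped; unresolvable templates are skipped with a warning.
#'
#' @param a3m_path alignment file.
#' @param template_dir directory of template PDB files.
#' @return list of `aligned_template` objects (template_id, mapping,
#'   template_sequence, ca, seq_similarity, seq_identity).
#' @export
load_alignments <- function(a3m_path, template_dir) {
  aln <- read_a3m(a3m_path)
  if (length(aln$ids) < 2) stop("alignment contains no templates")
  target <- gsub("-", "", toupper(aln$seqs[1]))
  L <- nchar(target)
  tchars <- strsplit(target, "")[[1]]
  out <- list()
  for (k in 2:length(aln$ids)) {
    id <- aln$ids[k]
    pdb_path <- file.path(template_dir, paste0(id, ".pdb"))
    if (!file.exists(pdb_path)) {
      warning("template '", id, "' has no coordinate file; skipped")
      next
    }
    tmpl <- read_pdb(pdb_path)
    m <- .a3m_mapping(aln$seqs[k], L)
    if (length(m$map) == 0) next
    ca <- atom_matrix(tmpl, "CA")
    ok <- m$map <= n_residues(tmpl) & !is.na(ca[pmin(m$map,
                                                     n_residues(tmpl)), 1])
    map <- m$map[ok]
    if (length(map) == 0) next
    qidx <- as.integer(names(map))
    st <- .aln_stats(tchars[qidx], toupper(m$taa[ok]))
    out[[length(out) + 1]] <- structure(
      list(template_id = id, mapping = map,
           template_sequence = extract_sequence(tmpl),
           ca = ca, seq_similarity = unname(st["sim"]),
           seq_identity = unname(st["id"])),
      class = "aligned_template")
  }
  if (length(out) == 0) stop("no usable templates in ", a3m_path)
  out
}

# pairwise template-template similarity via shared target columns
.template_pair_similarity <- function(t1, t2) {
  shared <- intersect(names(t1$mapping), names(t2$mapping))
  if (length(shared) == 0) return(0)
  a1 <- substring(t1$template_sequence, t1$mapping[shared],
                  t1$mapping[shared])
  a2 <- substring(t2$template_sequence, t2$mapping[shared],
                  t2$mapping[shared])
  mean(.column_similarity(a1, a2))
}

#' Cluster templates by sequence similarity
#'
#' Average-linkage agglomerative clustering on 1 - pairwise normalized
#' similarity, cut at `1 - similarity_threshold`. Templates are ordered by
#' id first, making the outcome independent of input order.
#'
#' @param templates list of `aligned_template`s.
#' @param similarity_threshold cluster similarity cut (default 0.8).
#' @return list of clusters, each with `members` (template list) and
#'   `ss_c` (mean member similarity to the target), `id_c` (mean member
#'   identity).
#' @export
cluster_templates <- function(templates, similarity_threshold = 0.8) {
  stopifnot(length(templates) >= 1)
  ids <- vapply(templates, function(t) t$template_id, "")
  templates <- templates[order(ids)]
  n <- length(templates)
  if (n == 1) {
    grp <- 1L
  } else {
    sim <- matrix(1, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <-
        .template_pair_similarity(templates[[i]], templates[[j]])
    }
    hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
    grp <- stats::cutree(hc, h = 1 - similarity_threshold)
  }
  lapply(unique(grp), function(g) {
    mem <- templates[grp == g]
    list(members = mem,
         ss_c = mean(vapply(mem, function(t) t$seq_similarity, 0)),
         id_c = mean(vapply(mem, function(t) t$seq_identity, 0)))
  })
}

#' Build a constraint ensemble
#'
#' For every template and every target index pair (i, j) mapped with both
#' C-alpha present and distance strictly below 15 A, one Gaussian
#' constraint mu_ijk is stored under the template's cluster.
#'
#' @param clusters output of [cluster_templates()].
#' @param target_length length of the target sequence.
#' @param gamma cluster-weighting constant (default 70).
#' @param max_dist constraint distance cutoff in Angstrom (default 15).
#' @return object of class `constraint_ensemble`.
#' @export
build_ensemble <- function(clusters, target_length, gamma = 70,
                           max_dist = 15) {
  rows <- list()
  for (c_idx in seq_along(clusters)) {
    for (t in clusters[[c_idx]]$members) {
      qidx <- as.integer(names(t$mapping))
      xyz <- t$ca[t$mapping, , drop = FALSE]
      if (length(qidx) < 2) next
      d <- cross_dist(xyz, xyz)
      sel <- which(upper.tri(d) & d < max_dist, arr.ind = TRUE)
      if (nrow(sel) == 0) next
      rows[[length(rows) + 1]] <- data.frame(
        i = qidx[sel[, 1]], j = qidx[sel[, 2]],
        cluster = c_idx, mu = d[sel])
    }
  }
  con <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(), j = integer(), cluster = integer(),
               mu = numeric())
  swap <- con$i > con$j
  tmpi <- con$i[swap]; con$i[swap] <- con$j[swap]; con$j[swap] <- tmpi
  con <- con[order(con$i, con$j, con$cluster), , drop = FALSE]
  structure(list(
    target_length = as.integer(target_length), gamma = gamma,
    max_dist = max_dist,
    ss_c = vapply(clusters, function(cl) cl$ss_c, 0),
    id_c = vapply(clusters, function(cl) cl$id_c, 0),
    constraints = con), class = "constraint_ensemble")
}

#' @export
print.constraint_ensemble <- function(x, ...) {
  cat(sprintf(
    "constraint_ensemble: target length %d, %d clusters, %d constraints\n",
    x$target_length, length(x$ss_c), nrow(x$constraints)))
  invisible(x)
}

#' Evaluate one pairwise scoring function
#'
#' s_ij(d) = sum_c w_c h_ijc(d) with h_ijc the mean of the cluster's
#' Gaussian constraints at d and w_c proportional to exp(gamma * SS_c),
#' normalized over the clusters that cover the pair.
#'
#' @param ensemble a `constraint_ensemble`.
#' @param i,j target residue indices (order irrelevant).
#' @param d_ij model C-alpha distance in Angstrom.
#' @return numeric in [0,1], or NA when the pair is absent from the
#'   ensemble (not evaluated).
#' @export
evaluate_pair <- function(ensemble, i, j, d_ij) {
  lo <- min(i, j); hi <- max(i, j)
  con <- ensemble$constraints
  sel <- con$i == lo & con$j == hi
  if (!any(sel)) return(NA_real_)
  con <- con[sel, , drop = FALSE]
  g <- exp(-0.5 * (d_ij - con$mu)^2)
  h <- tapply(g, con$cluster, mean)
  cl <- as.integer(names(h))
  ss <- ensemble$ss_c[cl]
  w <- exp(ensemble$gamma * (ss - max(ss)))   # stable softmax
  w <- w / sum(w)
  sum(w * h)
}

#' Score a model against a constraint ensemble
#'
#' For each residue i, evaluates s_ij at the model's C-alpha distances for
#' every partner j within 15 A that the ensemble covers, and averages.
#' Also returns the seven reliability features describing template support.
#'
#' @param ensemble a `constraint_ensemble`.
#' @param model a `structure3d` with length equal to the ensemble's target
#'   length.
#' @return list of class `disco_result`: `score` (per residue, NA when no
#'   pair could be evaluated) and a `features` data frame with
#'   `avg_n_clusters`, `avg_max_seq_similarity`, `avg_max_seq_identity`,
#'   `avg_variance`, `n_evaluated_pairs`, `n_total_pairs`,
#'   `fraction_evaluated`.
#' @export
disco_score <- function(ensemble, model) {
  n <- n_residues(model)
  if (n != ensemble$target_length)
    stop("model length ", n, " does not match ensemble target length ",
         ensemble$target_length)
  pairs <- ca_distance_map(model, ensemble$max_dist)
  con <- ensemble$constraints
  L1 <- n + 1
  pkey <- pairs$i * L1 + pairs$j
  ckey <- con$i * L1 + con$j

  # per-(pair,cluster) h values at the model distance
  hit <- match(ckey, pkey)
  have <- !is.na(hit)
  g <- exp(-0.5 * (pairs$d[hit[have]] - con$mu[have])^2)
  pc <- paste(ckey[have], con$cluster[have])
  h <- tapply(g, pc, mean)
  hkey <- as.numeric(vapply(strsplit(names(h), " "), `[`, "", 1))
  hcl <- as.integer(vapply(strsplit(names(h), " "), `[`, "", 2))
  ssmax <- tapply(ensemble$ss_c[hcl], hkey, max)
  w_raw <- exp(ensemble$gamma *
                 (ensemble$ss_c[hcl] -
                    as.numeric(ssmax[as.character(hkey)])))
  wsum <- tapply(w_raw, hkey, sum)
  w <- w_raw / as.numeric(wsum[as.character(hkey)])
  s_contrib <- w * as.numeric(h)
  s <- tapply(s_contrib, hkey, sum)
  skey <- as.numeric(names(s))

  # reliability ingredients per evaluated pair
  ncl <- tapply(hcl, hkey, length)                     # clusters covering
  max_ss <- tapply(ensemble$ss_c[hcl], hkey, max)
  max_id <- tapply(ensemble$id_c[hcl], hkey, max)
  mu_all <- con$mu[have]
  mu_key <- ckey[have]
  pooled_var <- tapply(mu_all, mu_key, function(m)
    if (length(m) > 1) stats::var(m) else 0)
  pv <- as.numeric(pooled_var[as.character(skey)])

  score <- rep(NA_real_, n)
  feats <- data.frame(avg_n_clusters = rep(NA_real_, n),
                      avg_max_seq_similarity = NA_real_,
                      avg_max_seq_identity = NA_real_,
                      avg_variance = NA_real_,
                      n_evaluated_pairs = 0L, n_total_pairs = 0L,
                      fraction_evaluated = 0)
  tot <- tabulate(c(pairs$i, pairs$j), nbins = n)
  feats$n_total_pairs <- tot
  if (length(s) > 0) {
    si <- floor(skey / L1); sj <- skey %% L1
    resid <- c(si, sj)
    vals <- data.frame(res = resid, s = c(s, s),
                       ncl = c(ncl, ncl), mss = c(max_ss, max_ss),
                       mid = c(max_id, max_id), pv = c(pv, pv))
    agg <- function(v) as.numeric(tapply(v, factor(vals$res,
                                                   levels = seq_len(n)),
                                         mean, default = NA))
    score <- agg(vals$s)
    feats$avg_n_clusters <- agg(vals$ncl)
    feats$avg_max_seq_similarity <- agg(vals$mss)
    feats$avg_max_seq_identity <- agg(vals$mid)
    feats$avg_variance <- agg(vals$pv)
    feats$n_evaluated_pairs <- tabulate(resid, nbins = n)
  }
  feats$fraction_evaluated <- ifelse(feats$n_total_pairs > 0,
                                     feats$n_evaluated_pairs /
                                       feats$n_total_pairs, 0)
  structure(list(score = score, features = feats,
                 gamma = ensemble$gamma), class = "disco_result")
}
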