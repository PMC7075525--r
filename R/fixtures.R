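# Synthetic-data generator. Everything the pipeline consumes can be
# produced here: idealized native structures (full backbone + CB built
# from ideal phi/psi segments), noise-perturbed "models" of controllable
# quality, perturbed/truncated/mutated "templates" with a consistent A3M
# alignment, and mock secondary-structure / accessibility predictor files.
# All generators are deterministic given their seed.

.PHI_PSI <- list(H = c(-57, -47), E = c(-139, 135))
.COIL_BASINS <- matrix(c(-70, 150, -60, -40, 55, 45), ncol = 2,
                       byrow = TRUE)

# sample a secondary-structure layout: helix/strand segments joined by
# short coil linkers
.sample_layout <- function(n) {
  out <- character(0)
  while (length(out) < n) {
    kind <- sample(c("H", "E", "C"), 1, prob = c(0.4, 0.3, 0.3))
    len <- switch(kind,
                  H = sample(6:12, 1),
                  E = sample(4:8, 1),
                  C = sample(2:5, 1))
    out <- c(out, rep(kind, len))
  }
  out[seq_len(n)]
}

.sample_sequence <- function(n) {
  # roughly natural composition, no 'X'
  freq <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.8,
            G = 7.1, H = 2.3, I = 6.0, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
            P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  sample(names(freq), n, replace = TRUE, prob = freq)
}

.segment_angles <- function(layout) {
  n <- length(layout)
  phi <- psi <- numeric(n)
  for (i in seq_len(n)) {
    if (layout[i] %in% c("H", "E")) {
      base <- .PHI_PSI[[layout[i]]]
      jit <- if (layout[i] == "H") 3 else 6
      phi[i] <- base[1] + stats::rnorm(1, 0, jit)
      psi[i] <- base[2] + stats::rnorm(1, 0, jit)
    } else {
      b <- .COIL_BASINS[sample.int(3, 1, prob = c(0.5, 0.35, 0.15)), ]
      phi[i] <- b[1] + stats::rnorm(1, 0, 10)
      psi[i] <- b[2] + stats::rnorm(1, 0, 10)
    }
  }
  cbind(phi, psi)
}

# build full backbone (N, CA, C, O) + CB coordinates from phi/psi with
# ideal bond geometry (trans peptide)
.build_backbone <- function(phi, psi) {
  n <- length(phi)
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           1.329, 116.2, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            1.458, 121.7, 180)        # omega trans
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           1.525, 111.2, phi[i])
    }
    nx <- if (i < n) psi[i] + 180 else 180
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, nx)
  }
  list(N = N, CA = CA, C = C, O = O)
}

.assemble_structure <- function(id, aa, bb) {
  n <- length(aa)
  rows <- list()
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (aa[i] != "G") {
      nm <- c(nm, "CB")
      xyz <- rbind(xyz, .cb_from_backbone(bb$N[i, ], bb$CA[i, ], bb$C[i, ]))
    }
    rows[[i]] <- data.frame(res = i, name = nm,
                            el = substr(nm, 1, 1), x = xyz[, 1],
                            y = xyz[, 2], z = xyz[, 3],
                            stringsAsFactors = FALSE)
  }
  structure3d(id = id, aa = aa, atoms = do.call(rbind, rows))
}

# TRUE when no heavy-atom pair of residues |i-j| >= 2 sits below the
# hard-sphere contact distance (the clash-score onset)
.is_clash_free <- function(s) {
  all(clash_score(s) == 0)
}

#' Generate an idealized native structure
#'
#' Full-backbone + C-beta chain built from ideal phi/psi segments
#' (helix/strand/coil per layout) with ideal trans-peptide bond geometry.
#' Candidate chains are rejection-resampled until clash-free (no
#' non-adjacent heavy-atom pair below the hard-sphere contact distance).
#'
#' @param length chain length in residues.
#' @param layout optional character vector over H/E/C, one per residue;
#'   sampled when NULL.
#' @param seed RNG seed (the caller's RNG state is preserved).
#' @param id structure id.
#' @param max_tries rejection-sampling bound.
#' @return a clash-free `structure3d`.
#' @export
make_native <- function(length = 40, layout = NULL, seed = NULL,
                        id = "native", max_tries = 80) {
  build <- function() {
    lay <- if (is.null(layout)) .sample_layout(length) else layout
    stopifnot(base::length(lay) == length)
    aa <- .sample_sequence(length)
    pp <- .segment_angles(lay)
    for (try in seq_len(max_tries)) {
      s <- .assemble_structure(id, aa, .build_backbone(pp[, 1], pp[, 2]))
      cs <- clash_score(s)
      if (all(cs == 0)) {
        attr(s, "layout") <- lay
        return(s)
      }
      # clashes are almost always local (segment transitions): resample
      # the angles in a small window around the clashing residues, and
      # only restart globally if that keeps failing
      if (try %% 12 == 0) {
        if (is.null(layout)) lay <- .sample_layout(length)
        pp <- .segment_angles(lay)
      } else {
        bad <- which(cs < 0)
        win <- unique(pmin(pmax(rep(bad, each = 5) + (-2:2), 1), length))
        pp[win, ] <- .segment_angles(lay[win])
      }
    }
    stop("could not place a clash-free chain in ", max_tries, " tries")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Generate perturbed models of a native
#'
#' Per noise amplitude a, a copy of the native with i.i.d. zero-mean
#' Gaussian displacement (sd = a, per atom and coordinate), optionally
#' with residue ranges deleted to emulate partial coverage.
#'
#' @param native a `structure3d`.
#' @param noise_amplitudes numeric vector of displacement sd values (A).
#' @param seed RNG seed.
#' @param delete optional list (one element per amplitude, or NULL
#'   entries) of residue index vectors to remove.
#' @return list of `structure3d` models.
#' @export
make_models <- function(native, noise_amplitudes, seed = NULL,
                        delete = NULL) {
  stopifnot(all(noise_amplitudes >= 0))
  gen <- function() {
    lapply(seq_along(noise_amplitudes), function(k) {
      a <- noise_amplitudes[k]
      s <- native
      s$id <- sprintf("%s_m%02d", native$id, k)
      if (a > 0) {
        sh <- matrix(stats::rnorm(3 * nrow(s$atoms), 0, a),
                     ncol = 3)
        s$atoms[, c("x", "y", "z")] <- s$atoms[, c("x", "y", "z")] + sh
      }
      del <- if (!is.null(delete)) delete[[k]] else NULL
      if (!is.null(del) && length(del) > 0) {
        keep <- setdiff(seq_len(n_residues(s)), del)
        at <- s$atoms[s$atoms$res %in% keep, , drop = FALSE]
        at$res <- match(at$res, keep)
        s <- structure3d(s$id, s$aa[keep], s$resno[keep],
                         s$inscode[keep], at)
      }
      s
    })
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate template structures and a consistent A3M alignment
#'
#' Templates are noise-perturbed copies of the native, truncated to a
#' coverage window and point-mutated to a requested sequence identity.
#' Written as PDB files named by template id plus one A3M whose master is
#' the target sequence.
#'
#' @param native a `structure3d` (the target).
#' @param dir output directory (created).
#' @param n_templates number of templates.
#' @param noise per-template coordinate noise sd (recycled).
#' @param coverage per-template covered fraction of the target (recycled).
#' @param identity per-template target sequence identity (recycled).
#' @param seed RNG seed.
#' @return list with `a3m` (path) and `template_dir` (path).
#' @export
make_templates_and_alignments <- function(native, dir,
                                          n_templates = 4,
                                          noise = 0.5, coverage = 1,
                                          identity = 0.9, seed = NULL) {
  gen <- function() {
    tdir <- file.path(dir, "templates")
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    L <- n_residues(native)
    noise <- rep_len(noise, n_templates)
    coverage <- rep_len(coverage, n_templates)
    identity <- rep_len(identity, n_templates)
    target <- extract_sequence(native)
    rows <- c(paste0(">target"), target)
    for (k in seq_len(n_templates)) {
      id <- sprintf("tmpl%02d", k)
      len <- max(3, round(coverage[k] * L))
      start <- if (len >= L) 1 else sample.int(L - len + 1, 1)
      idx <- start:(start + len - 1)
      aa <- native$aa
      n_mut <- round((1 - identity[k]) * length(idx))
      if (n_mut > 0) {
        pos <- sample(idx, n_mut)
        for (p in pos) aa[p] <- sample(setdiff(.AA20, aa[p]), 1)
      }
      at <- native$atoms[native$atoms$res %in% idx, , drop = FALSE]
      at$res <- match(at$res, idx)
      if (noise[k] > 0)
        at[, c("x", "y", "z")] <- at[, c("x", "y", "z")] +
          matrix(stats::rnorm(3 * nrow(at), 0, noise[k]), ncol = 3)
      tmpl <- structure3d(id, aa[idx], atoms = at)
      write_scored_pdb(tmpl, rep(0, length(idx)),
                       file.path(tdir, paste0(id, ".pdb")))
      aln <- rep("-", L)
      aln[idx] <- aa[idx]
      rows <- c(rows, paste0(">", id), paste(aln, collapse = ""))
    }
    a3m <- file.path(dir, "alignment.a3m")
    writeLines(rows, a3m)
    list(a3m = a3m, template_dir = tdir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# in-memory predictor inputs: 3-state collapse of the DSSP-equivalent
# states and 2-state burial, corrupted at error_rate with confidence
# anticorrelated with corruption
make_predictor_inputs <- function(native, error_rate = 0, seed = NULL,
                                  ss_acc = NULL) {
  gen <- function() {
    sa <- if (is.null(ss_acc)) assign_ss_and_acc(native) else ss_acc
    s3 <- ifelse(sa$state %in% c("G", "H", "I"), "H",
                 ifelse(sa$state %in% c("E", "B"), "E", "C"))
    n <- n_residues(native)
    wrong <- stats::runif(n) < error_rate
    pred <- s3
    for (i in which(wrong)) pred[i] <- sample(setdiff(.PRED3, s3[i]), 1)
    conf <- ifelse(wrong, sample(0:4, n, replace = TRUE),
                   sample(6:9, n, replace = TRUE))
    burial <- ifelse(sa$rel_acc < 0.25, "b", "e")
    accw <- stats::runif(n) < error_rate
    accpred <- ifelse(accw, ifelse(burial == "b", "e", "b"), burial)
    list(ss_state = pred, ss_conf = as.integer(conf), acc_state = accpred,
         true_state3 = s3, ss_acc = sa)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Generate mock predictor files
#'
#' Writes a PSIPRED vertical-format (.ss2) secondary-structure prediction
#' and an ACCpro-style two-state (.acc) burial prediction for the native,
#' corrupted at `error_rate` with prediction confidence anticorrelated
#' with corruption.
#'
#' @param native a `structure3d`.
#' @param dir output directory.
#' @param error_rate per-residue corruption probability in [0,1].
#' @param seed RNG seed.
#' @return list with `ss2` and `acc` file paths.
#' @export
make_predictor_files <- function(native, dir, error_rate = 0,
                                 seed = NULL) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inp <- make_predictor_inputs(native, error_rate, seed)
  n <- n_residues(native)
  pstate <- inp$ss_conf / 10 + 0.05
  rest <- (1 - pstate) / 2
  pC <- ifelse(inp$ss_state == "C", pstate, rest)
  pH <- ifelse(inp$ss_state == "H", pstate, rest)
  pE <- ifelse(inp$ss_state == "E", pstate, rest)
  ss2 <- file.path(dir, paste0(native$id, ".ss2"))
  writeLines(c("# PSIPRED VFORMAT (mock prediction)", "",
               sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                       seq_len(n), native$aa, inp$ss_state, pC, pH, pE)),
             ss2)
  acc <- file.path(dir, paste0(native$id, ".acc"))
  writeLines(c(paste0(">", native$id),
               paste(ifelse(inp$acc_state == "e", "e", "-"),
                     collapse = "")), acc)
  list(ss2 = ss2, acc = acc)
}

#' Emit a complete fixture directory tree
#'
#' natives/, models/, templates/<target>/, alignments/, predictions/ in
#' the standard plain-text formats, for one or more synthetic targets.
#'
#' @param dir output root.
#' @param n_targets number of targets.
#' @param length residues per target.
#' @param models_per_target models per target, noise spanning 0..noise_max.
#' @param noise_max maximum model perturbation sd (A).
#' @param seed RNG seed.
#' @return `dir`, invisibly.
#' @export
make_fixture_set <- function(dir, n_targets = 2, length = 30,
                             models_per_target = 4, noise_max = 2,
                             seed = 1) {
  for (sub in c("natives", "models", "templates", "alignments",
                "predictions"))
    dir.create(file.path(dir, sub), recursive = TRUE, showWarnings = FALSE)
  for (t in seq_len(n_targets)) {
    tid <- sprintf("target%02d", t)
    native <- make_native(length, seed = seed + 17 * t, id = tid)
    write_scored_pdb(native, rep(1, length),
                     file.path(dir, "natives", paste0(tid, ".pdb")))
    models <- make_models(native,
                          seq(0, noise_max,
                              length.out = models_per_target),
                          seed = seed + 17 * t + 1)
    for (m in models)
      write_scored_pdb(m, rep(1, n_residues(m)),
                       file.path(dir, "models", paste0(m$id, ".pdb")))
    tt <- make_templates_and_alignments(
      native, file.path(dir, "templates", tid), seed = seed + 17 * t + 2)
    file.copy(tt$a3m, file.path(dir, "alignments", paste0(tid, ".a3m")),
              overwrite = TRUE)
    make_predictor_files(native, file.path(dir, "predictions"),
                         error_rate = 0.1, seed = seed + 17 * t + 3)
  }
  invisible(dir)
}
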