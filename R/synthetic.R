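# Synthetic-structure generator: membrane proteins with TM helices crossing
# a slab and a globular extramembrane domain, soluble counterparts at
# controlled RMSD and sequence identity, secondary-structure strings, and
# functional sites with conserved shells. Every generator is reproducible
# under a fixed seed, and realized RMSD/identity are checked against their
# tolerance bands (the generator errors rather than drifting silently).

#' Ideal secondary-structure fragments
#'
#' `make_helix()` builds an ideal alpha-helix C-alpha trace (rise 1.5 A per
#' residue, radius 2.3 A, 100 degrees per residue, consecutive C-alpha
#' spacing about 3.8 A) along the +z axis. `make_strand()` builds an
#' extended strand at 3.5 A per residue. `make_coil()` builds a
#' self-avoiding random walk with 3.8 A steps and no two C-alpha closer
#' than 3 A.
#'
#' @param n residue count (>= 1).
#' @param seed RNG seed for `make_coil()` (`NULL`: use current RNG stream).
#' @param start first C-alpha position of the coil.
#' @return list with `coords` (n x 3) and `ss` (H/E/C string).
#' @export
make_helix <- function(n) {
  if (n < 1) abort("n must be >= 1")
  i <- seq_len(n) - 1
  theta <- i * 100 * pi / 180
  list(coords = cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * i),
       ss = strrep("H", n))
}

#' @rdname make_helix
#' @export
make_strand <- function(n) {
  if (n < 1) abort("n must be >= 1")
  i <- seq_len(n) - 1
  list(coords = cbind(rep(0, n), rep(0, n), 3.5 * i), ss = strrep("E", n))
}

#' @rdname make_helix
#' @export
make_coil <- function(n, seed = NULL, start = c(0, 0, 0)) {
  if (n < 1) abort("n must be >= 1")
  with_seed(seed, {
    coords <- matrix(NA_real_, n, 3)
    coords[1, ] <- start
    if (n > 1) {
      for (i in 2:n) {
        placed <- FALSE
        for (try in seq_len(200)) {
          step <- rnorm(3)
          step <- 3.8 * step / sqrt(sum(step^2))
          cand <- coords[i - 1, ] + step
          prev <- coords[seq_len(i - 2), , drop = FALSE]
          if (nrow(prev) == 0L ||
              min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= 3.0) {
            coords[i, ] <- cand
            placed <- TRUE
            break
          }
        }
        if (!placed) abort("self-avoiding walk failed; try another seed")
      }
    }
    list(coords = coords, ss = strrep("C", n))
  })
}

# Smooth connector between two anchor points: points along a quadratic
# Bezier bulging away from the membrane, roughly evenly spaced. Used to
# join secondary-structure fragments without chain clashes.
connector <- function(n, from, to, bulge = 6) {
  if (n < 1) return(matrix(numeric(), 0, 3))
  mid <- (from + to) / 2
  dir <- to - from
  perp <- c(-dir[2], dir[1], 0)
  if (sum(perp^2) < 1e-8) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  ctrl <- mid + bulge * perp + c(0, 0, sign(mid[3]) * bulge / 2)
  t <- seq_len(n) / (n + 1)
  b <- function(tt) (1 - tt)^2 %o% from + (2 * tt * (1 - tt)) %o% ctrl + tt^2 %o% to
  b(t)
}

random_sequence <- function(n) paste(sample(AA_LETTERS, n, replace = TRUE), collapse = "")

# Compact globular domain: three packed antiparallel helices joined by
# connectors, so the domain is a bundle rather than an extended loop.
make_globular_domain <- function(n) {
  if (n < 30) abort("globular domain needs at least 30 residues")
  link <- max(3L, n %/% 20L)
  h <- (n - 2L * link) %/% 3L
  extra <- n - 2L * link - 3L * h
  hl <- c(h + extra, h, h)
  pieces <- list(); ss <- character()
  x_off <- c(0, 9, 18)
  up <- c(TRUE, FALSE, TRUE)
  prev_end <- NULL
  for (k in 1:3) {
    hh <- make_helix(hl[k])
    coords <- hh$coords
    if (!up[k]) coords[, 3] <- -coords[, 3]
    coords[, 3] <- coords[, 3] - if (up[k]) (1.5 * (hl[k] - 1)) / 2 else -(1.5 * (hl[k] - 1)) / 2
    coords[, 1] <- coords[, 1] + x_off[k]
    if (!is.null(prev_end)) {
      conn <- connector(link, prev_end, coords[1, ])
      pieces[[length(pieces) + 1L]] <- conn
      ss <- c(ss, strrep("C", link))
    }
    pieces[[length(pieces) + 1L]] <- coords
    ss <- c(ss, hh$ss)
    prev_end <- coords[nrow(coords), ]
  }
  coords <- do.call(rbind, pieces)
  list(coords = coords, ss = paste(ss, collapse = ""))
}

#' Synthetic membrane-protein specification
#'
#' Parameters of one generated membrane protein. Defaults describe a
#' two-pass membrane protein with a 120-residue globular domain sitting
#' 25 A above the outer membrane surface, the typical scale of the screened
#' cohort (domains must exceed the 100-residue aligned-length threshold to
#' be detectable).
#'
#' @param n_tm_helices number of transmembrane helices.
#' @param tm_length residues per TM helix (20 residues spans the 30 A slab
#'   at the helical rise of 1.5 A per residue).
#' @param loop_length residues in short connecting loops.
#' @param domain_size residues in the globular extramembrane domain.
#' @param domain_distance distance (A) from the domain centroid to the
#'   nearer membrane surface.
#' @param domain_side `"outside"` (default) or `"inside"`.
#' @param z_half slab half-width (A); the slab is `[-z_half, z_half]`.
#' @param seed RNG seed.
#' @return a named list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_tm_helices = 2L, tm_length = 20L,
                           loop_length = 6L, domain_size = 120L,
                           domain_distance = 25, domain_side = "outside",
                           z_half = 15, seed = 1L) {
  stopifnot(n_tm_helices >= 1L, tm_length >= 10L, loop_length >= 2L,
            domain_size >= 30L, domain_distance >= 0,
            domain_side %in% c("inside", "outside"), z_half > 0)
  structure(list(n_tm_helices = n_tm_helices, tm_length = tm_length,
                 loop_length = loop_length, domain_size = domain_size,
                 domain_distance = domain_distance, domain_side = domain_side,
                 z_half = z_half, seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic membrane protein
#'
#' Builds a chain of `n_tm_helices` ideal TM helices spanning the slab
#' `[-z_half, z_half]`, joined by short loops alternating membrane sides,
#' with one loop carrying a compact globular domain (three packed helices)
#' whose centroid sits `domain_distance` Angstrom from the nearer membrane
#' surface on `domain_side`. Residue region labels (TM / inside / outside)
#' are derived from the construction geometry; the sequence is uniform
#' random. The whole structure is then placed in a random laboratory frame;
#' the returned annotation carries the transform back into the membrane
#' frame, emulating a PDBTM entry.
#'
#' @param spec a [synthetic_spec()].
#' @param id structure identifier.
#' @param sites_at optional integer positions (1-based, relative to the
#'   domain) at which to place functional site residues; the amino acid at
#'   each is set to `site_aa`.
#' @param site_aa amino acid(s) for the planted sites (default `"C"`).
#' @return list with `structure` ([protein_structure()]), `annotation`
#'   ([membrane_annotation()]), `ss` ([ss_string()]), `domain_range`
#'   (integer ordinal indices of the domain), `sites`
#'   ([functional_sites()] or NULL), and `spec`.
#' @export
make_membrane_protein <- function(spec = synthetic_spec(), id = "synthMP_A",
                                  sites_at = NULL, site_aa = "C") {
  with_seed(spec$seed, {
    zh <- spec$z_half
    pieces <- list(); ss <- character(); region <- character()
    domain_range <- NULL
    # topology convention: +z is "outside". The domain lands on the side the
    # first TM helix exits, so an "inside" domain starts the chain downward.
    up <- spec$domain_side == "outside"  # first helix direction
    cursor_x <- 0
    side_of <- function(z) if (z >= 0) "outside" else "inside"
    start_z <- if (up) -zh - 6 else zh + 6
    nter <- make_coil(3, start = c(-4, -4, start_z))
    pieces[[1]] <- nter$coords; ss <- nter$ss
    region <- rep(side_of(start_z), 3)
    prev_end <- nter$coords[3, ]
    domain_built <- FALSE
    for (k in seq_len(spec$n_tm_helices)) {
      hh <- make_helix(spec$tm_length)
      coords <- hh$coords
      span <- 1.5 * (spec$tm_length - 1)
      if (up) {
        coords[, 3] <- coords[, 3] - span / 2
      } else {
        coords[, 3] <- span / 2 - coords[, 3]
      }
      coords[, 1] <- coords[, 1] + cursor_x
      conn <- connector(2, prev_end, coords[1, ], bulge = 3)
      pieces[[length(pieces) + 1L]] <- conn
      ss <- c(ss, "CC")
      region <- c(region, rep(side_of(conn[1, 3]), 2))
      pieces[[length(pieces) + 1L]] <- coords
      ss <- c(ss, hh$ss)
      region <- c(region, rep("TM", spec$tm_length))
      prev_end <- coords[spec$tm_length, ]
      cursor_x <- cursor_x + 10
      top_z <- prev_end[3]
      if (!domain_built && k == 1L) {
        # the loop after TM1 carries the globular domain
        dom <- make_globular_domain(spec$domain_size)
        dc <- dom$coords
        dc <- sweep(dc, 2, colMeans(dc))
        target_z <- sign(top_z) * (zh + spec$domain_distance)
        dc <- sweep(dc, 2, c(cursor_x - 5, 12, target_z), "+")
        lead <- connector(spec$loop_length, prev_end, dc[1, ])
        n_before <- sum(vapply(pieces, nrow, 0L))
        pieces[[length(pieces) + 1L]] <- lead
        ss <- c(ss, strrep("C", spec$loop_length))
        region <- c(region, vapply(lead[, 3], side_of, ""))
        start_idx <- n_before + spec$loop_length + 1L
        pieces[[length(pieces) + 1L]] <- dc
        ss <- c(ss, dom$ss)
        region <- c(region, rep(side_of(target_z), nrow(dc)))
        domain_range <- start_idx:(start_idx + nrow(dc) - 1L)
        prev_end <- dc[nrow(dc), ]
        domain_built <- TRUE
      } else if (k < spec$n_tm_helices) {
        lp_z <- sign(top_z) * (zh + 5)
        lp <- make_coil(spec$loop_length,
                        start = prev_end + c(1, 1, sign(top_z) * 2))
        pieces[[length(pieces) + 1L]] <- lp$coords
        ss <- c(ss, lp$ss)
        region <- c(region, rep(side_of(lp_z), spec$loop_length))
        prev_end <- lp$coords[spec$loop_length, ]
      }
      up <- !up
    }
    coords <- do.call(rbind, pieces)
    ss_str <- paste(ss, collapse = "")
    n <- nrow(coords)
    seq <- strsplit(random_sequence(n), "")[[1]]
    if (!is.null(sites_at)) {
      site_aa <- rep_len(site_aa, length(sites_at))
      seq[domain_range[sites_at]] <- site_aa
    }
    # random laboratory frame; the annotation holds the inverse transform
    Rg <- random_rotation()
    tg <- rnorm(3, sd = 20)
    lab <- sweep(tcrossprod(coords, Rg), 2, tg, "+")
    st <- protein_structure(id, seq, lab)
    annot <- membrane_annotation(
      rotation = t(Rg),
      translation = as.numeric(-t(Rg) %*% tg),
      z_lower = -zh, z_upper = zh,
      region = region
    )
    validate_annotation(st, annot)
    sites <- if (!is.null(sites_at)) {
      functional_sites(id, seq_num = st$residues$seq_num[domain_range[sites_at]],
                       aa = site_aa)
    }
    list(structure = st, annotation = annot,
         ss = ss_string(id, ss_str), domain_range = domain_range,
         sites = sites, spec = spec)
  })
}

#' Generate a soluble counterpart of a membrane protein's domain
#'
#' Copies the extramembrane domain, perturbs the C-alpha coordinates with
#' isotropic Gaussian noise rescaled so the realized (post-superposition)
#' RMSD hits `target_rmsd` within 10%, and mutates the sequence so the
#' realized identity lands within 2 percentage points of
#' `target_identity`. With `shell_conservation = TRUE` the residues in the
#' first and second shells of `sites` (and the sites themselves) are
#' exempted from mutation; `keep_identical` forces specific domain-relative
#' positions to stay identical. The counterpart is returned in its own
#' random laboratory frame together with the ground-truth residue
#' correspondence.
#'
#' @param mem output of [make_membrane_protein()].
#' @param target_rmsd target C-alpha RMSD (Angstrom, >= 0) under the true
#'   mapping.
#' @param target_identity target percent sequence identity (0-100).
#' @param shell_conservation freeze first/second shell residues of `sites`.
#' @param sites [functional_sites()] on the membrane structure (required
#'   when `shell_conservation = TRUE`).
#' @param keep_identical integer domain-relative positions forced identical
#'   (counted toward the identity budget).
#' @param seed RNG seed.
#' @param id counterpart identifier.
#' @return list with `structure` (the counterpart), `mapping` (tibble
#'   `index_mem`, `index_sol`), `realized_rmsd`, `realized_identity`,
#'   `frozen` (domain-relative frozen positions).
#' @export
make_soluble_counterpart <- function(mem, target_rmsd = 2, target_identity = 10,
                                     shell_conservation = FALSE, sites = NULL,
                                     keep_identical = NULL, seed = 1L,
                                     id = "synthSOL_A") {
  stopifnot(target_rmsd >= 0, target_identity >= 0, target_identity <= 100)
  dom_idx <- mem$domain_range
  n <- length(dom_idx)
  mem_dom_coords <- structure_coords(mem$structure)[dom_idx, , drop = FALSE]
  mem_dom_seq <- mem$structure$residues$aa[dom_idx]
  with_seed(seed, {
    # --- coordinates ---
    if (target_rmsd == 0) {
      new_coords <- mem_dom_coords
      realized <- 0
    } else {
      E <- matrix(rnorm(3 * n), n, 3)
      s <- target_rmsd / sqrt(mean(rowSums(E^2)))
      realized <- NA_real_
      for (it in 1:4) {
        sup <- kabsch_superpose(mem_dom_coords, mem_dom_coords + s * E)
        realized <- sup$rmsd
        if (abs(realized - target_rmsd) / target_rmsd < 0.01) break
        s <- s * target_rmsd / realized
      }
      if (abs(realized - target_rmsd) / target_rmsd > 0.1) {
        abort("could not realize the target RMSD within 10%",
              class = "domex_generator_drift")
      }
      new_coords <- mem_dom_coords + s * E
    }
    # --- sequence ---
    frozen <- integer()
    if (!is.null(keep_identical)) frozen <- union(frozen, as.integer(keep_identical))
    if (shell_conservation) {
      if (is.null(sites)) abort("`sites` required when shell_conservation = TRUE")
      dom_structure <- protein_structure("dom", mem_dom_seq, mem_dom_coords)
      site_rel <- match(resolve_sites(mem$structure, sites), dom_idx)
      if (anyNA(site_rel)) abort("sites must lie inside the domain")
      part <- shells(dom_structure, site_rel)
      frozen <- union(frozen, c(part$site_residues, part$first_shell,
                                part$second_shell))
    }
    needed <- round(target_identity / 100 * n)
    if (length(frozen) > needed) {
      abort(paste0("identity target incompatible with ", length(frozen),
                   " frozen positions (budget ", needed, ")"),
            class = "domex_identity_conflict")
    }
    free <- setdiff(seq_len(n), frozen)
    keep_extra <- if (needed - length(frozen) > 0) {
      sample(free, needed - length(frozen))
    } else {
      integer()
    }
    mutate_at <- setdiff(free, keep_extra)
    new_seq <- mem_dom_seq
    for (i in mutate_at) {
      new_seq[i] <- sample(setdiff(AA_LETTERS, mem_dom_seq[i]), 1)
    }
    realized_identity <- 100 * mean(new_seq == mem_dom_seq)
    if (abs(realized_identity - target_identity) > 2) {
      abort("realized identity outside the 2-point tolerance band",
            class = "domex_generator_drift")
    }
    # --- own laboratory frame ---
    Rg <- random_rotation()
    tg <- rnorm(3, sd = 20)
    lab <- sweep(tcrossprod(new_coords, Rg), 2, tg, "+")
    sol <- protein_structure(id, new_seq, lab)
    list(structure = sol,
         mapping = tibble::tibble(index_mem = dom_idx, index_sol = seq_len(n)),
         realized_rmsd = realized,
         realized_identity = realized_identity,
         frozen = sort(frozen))
  })
}

#' Generate an unrelated decoy soluble structure
#'
#' A globular three-helix bundle with an independent random sequence and its
#' own random frame; used as the non-counterpart candidate in screening
#' cohorts.
#'
#' @param n residue count.
#' @param seed RNG seed.
#' @param id identifier.
#' @return list with `structure` and `ss` string.
#' @export
make_decoy_soluble <- function(n = 120L, seed = 1L, id = "decoy_A") {
  with_seed(seed, {
    dom <- make_globular_domain(n)
    # randomize helix lengths a little by resampling a coil tail
    Rg <- random_rotation()
    tg <- rnorm(3, sd = 20)
    coords <- sweep(tcrossprod(dom$coords, Rg), 2, tg, "+")
    # decoys get extra per-residue jitter so they are not trivially the
    # same ideal bundle as a generated domain
    coords <- coords + matrix(rnorm(3 * n, sd = 4), n, 3)
    list(structure = protein_structure(id, random_sequence(n), coords),
         ss = ss_string(id, dom$ss))
  })
}

#' Generate a labelled, scored pair cohort for SSEA training
#'
#' Emulates the training-set construction: positives are structurally
#' similar pairs (RMSD below 5 A) and negatives dissimilar pairs (RMSD
#' above 10 A), both restricted to the 5-15% sequence-identity range, with
#' SSEA scores drawn from a configurable model:
#' \describe{
#'   \item{`"crossing50"`}{positives ~ Normal(65, 10), negatives ~
#'     Normal(35, 10), clamped to 0-100. The two densities cross at 50 and
#'     at the published training-set sizes (923 vs 210) their rank
#'     separation reproduces the published order of magnitude
#'     (p below 1e-100), which is what fixes the spread.}
#'   \item{`"degenerate"`}{positives scored 80, negatives 20.}
#'   \item{`"logistic"`}{scores uniform on 0-100 and class drawn so that
#'     P(similar | score s) follows `plogis((s - 50) / 8)` when
#'     `n_pos = n_neg`.}
#' }
#'
#' @param n_pos,n_neg cohort sizes.
#' @param score_model one of `"crossing50"`, `"degenerate"`, `"logistic"`.
#' @param seed RNG seed.
#' @return tibble with `pair_id`, `label` (`"pos"`/`"neg"`), `rmsd`,
#'   `identity`, `score`, `similar`.
#' @export
make_pair_cohort <- function(n_pos, n_neg,
                             score_model = c("crossing50", "degenerate", "logistic"),
                             seed = 1L) {
  score_model <- match.arg(score_model)
  stopifnot(n_pos >= 1L, n_neg >= 1L)
  with_seed(seed, {
    clamp <- function(x) pmin(100, pmax(0, x))
    p_sim <- function(s) stats::plogis((s - 50) / 8)
    draw_logistic <- function(n, positive) {
      out <- numeric(0)
      while (length(out) < n) {
        s <- runif(2L * (n - length(out)) + 10L, 0, 100)
        pr <- if (positive) p_sim(s) else 1 - p_sim(s)
        out <- c(out, s[runif(length(s)) < pr])
      }
      out[seq_len(n)]
    }
    scores_pos <- switch(score_model,
      crossing50 = clamp(rnorm(n_pos, 65, 10)),
      degenerate = rep(80, n_pos),
      logistic = draw_logistic(n_pos, TRUE)
    )
    scores_neg <- switch(score_model,
      crossing50 = clamp(rnorm(n_neg, 35, 10)),
      degenerate = rep(20, n_neg),
      logistic = draw_logistic(n_neg, FALSE)
    )
    tibble::tibble(
      pair_id = paste0("pair", seq_len(n_pos + n_neg)),
      label = rep(c("pos", "neg"), c(n_pos, n_neg)),
      rmsd = c(runif(n_pos, 0.5, 5), runif(n_neg, 10, 20)),
      identity = runif(n_pos + n_neg, 5, 15),
      score = c(scores_pos, scores_neg),
      similar = rep(c(TRUE, FALSE), c(n_pos, n_neg))
    )
  })
}
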