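# End-to-end orchestration: simulate or load a cohort, align, screen,
# assign sides, score functional-site shells, measure membrane distances,
# and train the SSEA cutoff, with a headline summary.

#' Pipeline configuration
#'
#' Thresholds default to the published selection values (RMSD 5 A, aligned
#' length 100, TM-score 0.5, 30% redundancy, 90% domain coverage, 5 A shell
#' radius, PAM-250 gap -11) and the published SSEA training protocol
#' (100 pairs per set, 1000 replicates).
#'
#' @param screen a [screen_config()] list.
#' @param shell_radius shell radius in Angstrom.
#' @param gap PAM-250 gap penalty.
#' @param ssea_n_sample,ssea_reps SSEA training protocol sizes.
#' @param seed RNG seed for every stochastic stage.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(screen = screen_config(), shell_radius = 5, gap = -11,
                       ssea_n_sample = 100L, ssea_reps = 1000L, seed = 1L) {
  stopifnot(shell_radius > 0, gap < 0, ssea_n_sample > 0, ssea_reps > 0)
  structure(list(screen = screen, shell_radius = shell_radius, gap = gap,
                 ssea_n_sample = ssea_n_sample, ssea_reps = ssea_reps,
                 seed = seed),
            class = "run_config")
}

#' Simulate a membrane/soluble comparison cohort
#'
#' Generates `n_membrane` synthetic membrane proteins. A fraction
#' `frac_partner` of them receive a true soluble counterpart of their
#' extramembrane domain (at the given RMSD/identity); the rest are paired
#' with an unrelated decoy structure, so the screening stage has real work
#' to do. Each membrane protein carries two planted cysteine functional
#' sites in its domain; true counterparts keep the sites identical.
#'
#' @param n_membrane number of membrane proteins.
#' @param frac_partner fraction given a true counterpart (default 0.67,
#'   the observed fraction of membrane structures with a soluble partner).
#' @param target_rmsd,target_identity counterpart perturbation levels.
#' @param frac_outside fraction of domains planted on the outside face
#'   (default 0.957, the observed outside fraction).
#' @param seed RNG seed.
#' @return a list of cohort entries; each has `mem` (generator output),
#'   `sol` (`structure`, `ss`, and truth fields for true counterparts),
#'   `truth` (logical: true counterpart?).
#' @export
simulate_study <- function(n_membrane = 30L, frac_partner = 0.67,
                           target_rmsd = 2, target_identity = 10,
                           frac_outside = 0.957, seed = 1L) {
  with_seed(seed, {
    entry_seeds <- sample.int(1e6, n_membrane * 4L)
    has_partner <- runif(n_membrane) < frac_partner
    is_outside <- runif(n_membrane) < frac_outside
    purrr::map(seq_len(n_membrane), function(i) {
      sp <- synthetic_spec(
        domain_side = if (is_outside[i]) "outside" else "inside",
        domain_distance = runif(1, 15, 35),
        seed = entry_seeds[4 * i - 3]
      )
      mid <- sprintf("synthMP%03d_A", i)
      mem <- make_membrane_protein(sp, id = mid, sites_at = c(40L, 45L),
                                   site_aa = "C")
      sol <- if (has_partner[i]) {
        cp <- make_soluble_counterpart(
          mem, target_rmsd = target_rmsd, target_identity = target_identity,
          keep_identical = match(resolve_sites(mem$structure, mem$sites),
                                 mem$domain_range),
          seed = entry_seeds[4 * i - 2],
          id = sprintf("synthSOL%03d_A", i)
        )
        # counterpart inherits the domain's secondary structure string
        dom_ss <- substr(mem$ss$ss, min(mem$domain_range), max(mem$domain_range))
        cp$ss <- ss_string(cp$structure$id, dom_ss)
        cp$sites <- functional_sites(
          cp$structure$id,
          seq_num = cp$structure$residues$seq_num[
            match(resolve_sites(mem$structure, mem$sites), mem$domain_range)],
          aa = mem$sites$aa
        )
        cp
      } else {
        dc <- make_decoy_soluble(n = structure_length(mem$structure) %/% 2L,
                                 seed = entry_seeds[4 * i - 1],
                                 id = sprintf("decoy%03d_A", i))
        list(structure = dc$structure, ss = dc$ss, mapping = NULL,
             sites = NULL)
      }
      list(mem = mem, sol = sol, truth = has_partner[i])
    })
  })
}

#' Run the full domain-exchange analysis on a cohort
#'
#' For every membrane/soluble candidate pair: structural alignment
#' ([align_structures()]), screening ([screen_pair()]), topology side,
#' conserved functional sites and shell-vs-rest similarity
#' ([shell_vs_rest()]) where sites exist, membrane distance of the
#' ground-truth domain, a Mann-Whitney comparison of membrane distances
#' between domains with and without a passing soluble partner, and SSEA
#' cutoff training on a synthetic scored cohort. Deterministic given the
#' config seed.
#'
#' @param cohort output of [simulate_study()] (or a list shaped like it).
#' @param config a [run_config()].
#' @param ssea_cohort optional scored pair cohort for the SSEA stage; by
#'   default one is generated at the published training sizes (923
#'   positives, 210 negatives) from the config seed.
#' @return an object of class `domex_run`: `pairs` (per-pair decision
#'   tibble), `distances` (per-domain membrane distances with group),
#'   `membrane_test` (`mw_test` or NULL), `ssea` (`ssea_cutoff`), and
#'   `summary` (one-row tibble of headline numbers).
#' @export
run_domain_exchange <- function(cohort, config = run_config(),
                                ssea_cohort = NULL) {
  if (length(cohort) == 0L) {
    return(structure(list(pairs = tibble::tibble(), distances = tibble::tibble(),
                          membrane_test = NULL, ssea = NULL,
                          summary = tibble::tibble(n_membrane = 0L)),
                     class = "domex_run"))
  }
  rows <- purrr::map(cohort, function(entry) {
    aln <- align_structures(entry$mem$structure, entry$sol$structure,
                            ss_a = entry$mem$ss, ss_b = entry$sol$ss)
    dec <- screen_pair(aln, entry$mem$annotation, membrane_side = "a",
                       config = config$screen)
    shell_ok <- NA
    n_conserved <- NA_integer_
    if (dec$passed && !is.null(entry$mem$sites) && !is.null(entry$sol$sites)) {
      sv <- tryCatch(
        shell_vs_rest(aln, entry$mem$sites, entry$sol$sites,
                      entry$mem$structure, entry$sol$structure,
                      radius = config$shell_radius, gap = config$gap),
        domex_no_conserved_sites = function(e) NULL
      )
      if (!is.null(sv)) {
        shell_ok <- sv$shell_per_column > sv$rest_per_column
        n_conserved <- nrow(sv$conserved_sites)
      } else {
        n_conserved <- 0L
      }
    }
    dist <- domain_membrane_distance(entry$mem$domain_range,
                                     entry$mem$structure,
                                     entry$mem$annotation)
    dplyr::bind_cols(
      dec,
      tibble::tibble(truth = entry$truth,
                     n_conserved_sites = n_conserved,
                     shell_more_conserved = shell_ok,
                     membrane_distance = dist$distance,
                     domain_side_geom = dist$side)
    )
  }) |> dplyr::bind_rows()

  distances <- rows |>
    dplyr::transmute(domain_id = .data$id_a, distance = .data$membrane_distance,
                     group = dplyr::if_else(.data$passed, "with_counterpart",
                                            "without_counterpart"))
  membrane_test <- if (dplyr::n_distinct(distances$group) == 2L) {
    membrane_distance_test(distances)
  }

  if (is.null(ssea_cohort)) {
    ssea_cohort <- make_pair_cohort(923L, 210L, "crossing50",
                                    seed = config$seed + 101L)
  }
  ssea_fit <- train_ssea_cutoff(
    ssea_cohort$score[ssea_cohort$label == "pos"],
    ssea_cohort$score[ssea_cohort$label == "neg"],
    n_sample = config$ssea_n_sample, reps = config$ssea_reps,
    seed = config$seed
  )

  passed <- dplyr::filter(rows, .data$passed)
  shell_assessed <- dplyr::filter(rows, !is.na(.data$shell_more_conserved))
  summary <- tibble::tibble(
    n_membrane = nrow(rows),
    frac_with_partner = mean(rows$passed),
    mean_rmsd = mean(passed$rmsd),
    mean_aligned_length = mean(passed$aligned_length),
    frac_outside = mean(passed$side == "outside"),
    frac_site_sharing = mean(passed$n_conserved_sites > 0, na.rm = TRUE),
    frac_shell_conserved = if (nrow(shell_assessed)) {
      mean(shell_assessed$shell_more_conserved)
    } else {
      NA_real_
    },
    membrane_p = if (!is.null(membrane_test)) membrane_test$p_value else NA_real_,
    ssea_cutoff = ssea_fit$cutoff
  )
  structure(list(pairs = rows, distances = distances,
                 membrane_test = membrane_test, ssea = ssea_fit,
                 summary = summary),
            class = "domex_run")
}

#' @export
print.domex_run <- function(x, ...) {
  cat("<domex_run> ", nrow(x$pairs), " candidate pair(s)\n", sep = "")
  if (nrow(x$pairs) > 0) print(x$summary)
  invisible(x)
}

#' @rdname tidy_domex
#' @method tidy domex_run
#' @export
tidy.domex_run <- function(x, ...) x$pairs

#' @rdname tidy_domex
#' @method glance domex_run
#' @export
glance.domex_run <- function(x, ...) x$summary

#' Write / read a simulated cohort as files
#'
#' Serializes each cohort entry into the on-disk layout the pipeline
#' assumes: C-alpha PDB files, membrane-annotation JSON sidecars, H/E/C
#' secondary-structure files and site TSVs, plus a `pairs.tsv` manifest.
#' `read_study()` loads the directory back into the in-memory cohort shape
#' (ground-truth fields reduced to what the files carry).
#'
#' @param cohort output of [simulate_study()].
#' @param dir target directory (created if needed).
#' @return `write_study()` returns `dir` invisibly; `read_study()` a
#'   cohort list.
#' @export
write_study <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::imap(cohort, function(entry, i) {
    mid <- entry$mem$structure$id
    sid <- entry$sol$structure$id
    write_pdb_ca(entry$mem$structure, file.path(dir, paste0(mid, ".pdb")))
    write_membrane_annotation(entry$mem$annotation,
                              file.path(dir, paste0(mid, ".json")))
    write_ss(entry$mem$ss, file.path(dir, paste0(mid, ".ss")))
    if (!is.null(entry$mem$sites)) {
      write_sites(entry$mem$sites, file.path(dir, paste0(mid, ".sites")))
    }
    write_pdb_ca(entry$sol$structure, file.path(dir, paste0(sid, ".pdb")))
    if (!is.null(entry$sol$ss)) {
      write_ss(entry$sol$ss, file.path(dir, paste0(sid, ".ss")))
    }
    if (!is.null(entry$sol$sites)) {
      write_sites(entry$sol$sites, file.path(dir, paste0(sid, ".sites")))
    }
    tibble::tibble(id_mem = mid, id_sol = sid,
                   domain_start = min(entry$mem$domain_range),
                   domain_end = max(entry$mem$domain_range),
                   truth = entry$truth)
  }) |> dplyr::bind_rows()
  write_report(manifest, file.path(dir, "pairs.tsv"))
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- read_report(file.path(dir, "pairs.tsv"))
  purrr::pmap(manifest, function(id_mem, id_sol, domain_start, domain_end, truth) {
    chain_of <- function(id) sub(".*_", "", id)
    mem_st <- read_pdb_chain(file.path(dir, paste0(id_mem, ".pdb")), chain_of(id_mem))
    mem_st$id <- id_mem
    sol_st <- read_pdb_chain(file.path(dir, paste0(id_sol, ".pdb")), chain_of(id_sol))
    sol_st$id <- id_sol
    sites_path <- file.path(dir, paste0(id_mem, ".sites"))
    sol_sites_path <- file.path(dir, paste0(id_sol, ".sites"))
    sol_ss_path <- file.path(dir, paste0(id_sol, ".ss"))
    list(
      mem = list(
        structure = mem_st,
        annotation = read_membrane_annotation(file.path(dir, paste0(id_mem, ".json"))),
        ss = read_ss(file.path(dir, paste0(id_mem, ".ss"))),
        sites = if (file.exists(sites_path)) read_sites(sites_path, id_mem),
        domain_range = domain_start:domain_end
      ),
      sol = list(
        structure = sol_st,
        ss = if (file.exists(sol_ss_path)) read_ss(sol_ss_path),
        sites = if (file.exists(sol_sites_path)) read_sites(sol_sites_path, id_sol)
      ),
      truth = truth
    )
  })
}
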