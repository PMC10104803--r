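# Seeded synthetic datasets with the exact statistical structure every
# analysis stage assumes: each generator draws data from the forward
# model its target fitter inverts (4PL, operational equation, one-site
# hyperbola/logistic, two-ligand mass-action kinetics, single
# exponential), plus toy coordinate sets with controllable B-factors.
# Ground truth travels in a sidecar, never inside the data table.

.assay_kinds <- c("dose_response_hill", "dose_response_operational",
                  "saturation", "competition", "kinetics_association",
                  "kinetics_dissociation", "structure_fixture")

#' Specify a synthetic dataset
#'
#' @param assay_kind one of `r paste0('"', .assay_kinds, '"', collapse = ", ")`.
#' @param true_params named list of ground-truth parameters for the
#'   target module (see [generate()] for the fields each kind uses).
#' @param design dose/time/concentration grids and replicate counts;
#'   unspecified entries fall back to kind-specific defaults.
#' @param noise list with `model = "gaussian"`, `sigma`, and `type`
#'   (`"percent"` of the signal scale, the default, or `"absolute"`).
#' @param seed integer RNG seed; a fixed seed makes [generate()]
#'   byte-reproducible.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(assay_kind, true_params = list(), design = list(),
                           noise = list(model = "gaussian", sigma = 0,
                                        type = "percent"),
                           seed = 1L) {
  if (!assay_kind %in% .assay_kinds) {
    stop("unknown assay_kind: ", assay_kind, call. = FALSE)
  }
  noise$model <- noise$model %||% "gaussian"
  noise$sigma <- noise$sigma %||% 0
  noise$type <- noise$type %||% "percent"
  if (noise$model != "gaussian") stop("only gaussian noise is supported",
                                      call. = FALSE)
  if (noise$sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(list(assay_kind = assay_kind, true_params = true_params,
                 design = design, noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

noise_sd <- function(noise, scale) {
  if (noise$type == "absolute") noise$sigma else noise$sigma / 100 * scale
}

#' Generate a synthetic dataset from a spec
#'
#' Data are drawn from the exact forward model of the target analysis
#' stage with additive Gaussian noise; the returned `truth` sidecar
#' records the generating parameters and seed. Identical specs generate
#' identical data.
#'
#' Parameter fields by kind (defaults in parentheses):
#' * `dose_response_hill`: `basal` (0), `emax` (100), `log_ec50` (-7.5),
#'   `hill_n` (1); design `doses` (8 log-spaced in 1e-10..1e-4 M),
#'   `replicates` (1).
#' * `dose_response_operational`: `em` (100), `trans_n` (1), `ligands` =
#'   data frame with `ligand`, `log_tau`, `log_ka`, and optional
#'   `pathway` for multi-pathway designs; same dose design.
#' * `saturation`: `kd` (0.080e-9 M), `bmax` (2.7), `ns_slope`
#'   (0.1 * bmax per nM); design `conc` (8 points, 0.01-1 nM).
#' * `competition`: `ki` (3.5e-9 M), `top` (100), `bottom` (0),
#'   `hill_n` (1), `radioligand_conc` (0.25e-9 M), `radioligand_kd`
#'   (0.080e-9 M); design `conc` (9 points, 1e-11..1e-5 M),
#'   `replicates` (3).
#' * `kinetics_association`: `k1` (3e7 /M/s), `k2` (3e-3 /s), `conc_l`
#'   (0.25e-9 M), `k3` (1e6 /M/s), `k4` (5e-3 /s), `bmax_scale` (100);
#'   design `competitor_concs` (0, 3, 10, 30 nM), `t_grid` (20 points,
#'   0-3600 s).
#' * `kinetics_dissociation`: `koff` (1e-3 /s), `y0` (100), `ns` (10);
#'   design `t_grid`.
#' * `structure_fixture`: ideal poly-alanine alpha-helix; `b` = per-
#'   residue B-factors (recycled; default 20..40 ramp); design `n_res`
#'   (20), `chain` ("A").
#'
#' @param spec a [synthetic_spec()].
#' @return list with `data` (in the matching module's input format) and
#'   `truth` (generating parameters, design and seed).
#' @export
generate <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, switch(
    spec$assay_kind,
    dose_response_hill = gen_hill(spec),
    dose_response_operational = gen_operational(spec),
    saturation = gen_saturation(spec),
    competition = gen_competition(spec),
    kinetics_association = gen_kin_assoc(spec),
    kinetics_dissociation = gen_kin_dissoc(spec),
    structure_fixture = gen_structure(spec)
  ))
}

gen_hill <- function(spec) {
  p <- spec$true_params
  basal <- p$basal %||% 0; emax <- p$emax %||% 100
  log_ec50 <- p$log_ec50 %||% -7.5; hill_n <- p$hill_n %||% 1
  doses <- spec$design$doses %||% lseq(1e-10, 1e-4, 8)
  reps <- spec$design$replicates %||% 1L
  sdv <- noise_sd(spec$noise, abs(emax - basal))
  rows <- expand.grid(replicate = as.character(seq_len(reps)), dose = doses,
                      stringsAsFactors = FALSE)
  mu <- hill_model(rows$dose, basal, emax, log_ec50, hill_n)
  data <- data.frame(ligand = p$ligand %||% "L1",
                     receptor = p$receptor %||% "R1",
                     pathway = p$pathway %||% "P1",
                     dose = rows$dose,
                     signal = mu + rnorm(nrow(rows), 0, sdv),
                     replicate = rows$replicate,
                     stringsAsFactors = FALSE)
  class(data) <- c("dose_response_dataset", "data.frame")
  list(data = data,
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    basal = basal, emax = emax, log_ec50 = log_ec50,
                    hill_n = hill_n, sigma = spec$noise$sigma))
}

default_op_ligands <- function() {
  data.frame(
    ligand = c("ref", "test", "ref", "test"),
    pathway = c("camp", "camp", "arrestin", "arrestin"),
    log_tau = c(0.8, -0.2, 0.8, -0.1),
    log_ka = c(-6.5, -6.9, -6.5, -7.5),
    stringsAsFactors = FALSE
  )  # log_r: ref 7.3 both; test 6.7 (camp), 7.4 (arrestin); ddlog = 0.7
}

gen_operational <- function(spec) {
  p <- spec$true_params
  em <- p$em %||% 100; n <- p$trans_n %||% 1
  ligands <- p$ligands %||% default_op_ligands()
  if (is.null(ligands$pathway)) ligands$pathway <- "P1"
  doses <- spec$design$doses %||% lseq(1e-10, 1e-4, 8)
  reps <- spec$design$replicates %||% 1L
  sdv <- noise_sd(spec$noise, em)
  curves <- lapply(seq_len(nrow(ligands)), function(i) {
    rows <- expand.grid(replicate = as.character(seq_len(reps)),
                        dose = doses, stringsAsFactors = FALSE)
    mu <- op_model_partial(rows$dose, em, n, 10^ligands$log_tau[i],
                           10^ligands$log_ka[i])
    normalized_curve(rows$dose, mu + rnorm(nrow(rows), 0, sdv),
                     replicate = rows$replicate,
                     ligand = ligands$ligand[i],
                     receptor = p$receptor %||% "R1",
                     pathway = ligands$pathway[i])
  })
  ligands$log_r <- ligands$log_tau - ligands$log_ka
  list(data = curves,
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    em = em, trans_n = n, ligands = ligands,
                    sigma = spec$noise$sigma))
}

gen_saturation <- function(spec) {
  p <- spec$true_params
  kd <- p$kd %||% 0.080e-9; bmax <- p$bmax %||% 2.7
  ns_slope <- p$ns_slope %||% (0.1 * bmax / 1e-9)
  conc <- spec$design$conc %||% lseq(0.01e-9, 1e-9, 8)
  sdv <- noise_sd(spec$noise, bmax)
  specific <- bmax * conc / (kd + conc)
  ns <- ns_slope * conc
  data <- data.frame(
    conc = conc,
    total = specific + ns + rnorm(length(conc), 0, sdv),
    nonspecific = ns + rnorm(length(conc), 0, sdv)
  )
  list(data = data,
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    kd = kd, bmax = bmax, ns_slope = ns_slope,
                    sigma = spec$noise$sigma))
}

gen_competition <- function(spec) {
  p <- spec$true_params
  ki <- p$ki %||% 3.5e-9
  l <- p$radioligand_conc %||% 0.25e-9
  kdl <- p$radioligand_kd %||% 0.080e-9
  top <- p$top %||% 100; bottom <- p$bottom %||% 0
  hill_n <- p$hill_n %||% 1
  ic50 <- ki * (1 + l / kdl)
  conc <- spec$design$conc %||% lseq(1e-11, 1e-5, 9)
  reps <- spec$design$replicates %||% 3L
  sdv <- noise_sd(spec$noise, abs(top - bottom))
  rows <- expand.grid(replicate = seq_len(reps), conc = conc)
  mu <- bottom + (top - bottom) /
    (1 + 10^(hill_n * (log10(rows$conc) - log10(ic50))))
  data <- data.frame(conc = rows$conc, replicate = rows$replicate,
                     binding = mu + rnorm(nrow(rows), 0, sdv))
  list(data = data,
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    ki = ki, ic50 = ic50, radioligand_conc = l,
                    radioligand_kd = kdl, top = top, bottom = bottom,
                    hill_n = hill_n, sigma = spec$noise$sigma))
}

gen_kin_assoc <- function(spec) {
  p <- spec$true_params
  rl <- radioligand_kinetics(p$k1 %||% 3e7, p$k2 %||% 3e-3,
                             p$conc_l %||% 0.25e-9)
  k3 <- p$k3 %||% 1e6; k4 <- p$k4 %||% 5e-3
  bmax <- p$bmax_scale %||% 100
  concs <- spec$design$competitor_concs %||% c(0, 3e-9, 10e-9, 30e-9)
  t_grid <- spec$design$t_grid %||% seq(60, 3600, length.out = 20)
  plateau <- bmax * rl$conc_l / (rl$conc_l + rl$kd_l)
  sdv <- noise_sd(spec$noise, plateau)
  traces <- lapply(seq_along(concs), function(i) {
    mu <- mm_bound(t_grid, rl, k3, k4, concs[i], bmax)
    kinetic_trace(trace_id = sprintf("assoc_%02d", i),
                  trace_type = "association",
                  competitor = "competitor", competitor_conc = concs[i],
                  time = t_grid, signal = mu + rnorm(length(t_grid), 0, sdv))
  })
  list(data = structure(traces, class = "kinetic_dataset"),
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    k1 = rl$k1, k2 = rl$k2, conc_l = rl$conc_l,
                    k3 = k3, k4 = k4, bmax_scale = bmax,
                    kinetic_kd = k4 / k3, sigma = spec$noise$sigma))
}

gen_kin_dissoc <- function(spec) {
  p <- spec$true_params
  koff <- p$koff %||% 1e-3; y0 <- p$y0 %||% 100; ns <- p$ns %||% 10
  t_grid <- spec$design$t_grid %||% seq(0, 3600, length.out = 20)
  sdv <- noise_sd(spec$noise, abs(y0 - ns))
  mu <- ns + (y0 - ns) * exp(-koff * t_grid)
  trace <- kinetic_trace(trace_id = "dissoc_01",
                         trace_type = "dissociation",
                         time = t_grid,
                         signal = mu + rnorm(length(t_grid), 0, sdv))
  list(data = trace,
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    koff = koff, y0 = y0, ns = ns,
                    sigma = spec$noise$sigma))
}

# Ideal poly-alanine alpha-helix with controllable per-residue B-factors.
gen_structure <- function(spec) {
  p <- spec$true_params
  n_res <- spec$design$n_res %||% 20L
  chain <- spec$design$chain %||% "A"
  b <- rep_len(p$b %||% seq(20, 40, length.out = n_res), n_res)
  sdv <- noise_sd(spec$noise, mean(b))
  # CA trace on a helix: 100 deg twist, 1.5 A rise, 2.3 A radius;
  # backbone N/C/O placed by small fixed offsets from CA.
  atoms <- list()
  offsets <- list(N = c(-0.8, -1.0, -0.6), CA = c(0, 0, 0),
                  C = c(0.9, 0.9, 0.5), O = c(1.0, 1.9, 0.9),
                  CB = c(1.2, -1.0, 0.5))
  for (i in seq_len(n_res)) {
    theta <- (i - 1) * 100 * pi / 180
    ca <- c(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    bi <- b[i] + if (sdv > 0) rnorm(1, 0, sdv) else 0
    for (nm in names(offsets)) {
      xyz <- ca + offsets[[nm]]
      atoms[[length(atoms) + 1L]] <- data.frame(
        chain = chain, resno = i, insert = "", resid = "ALA", atom = nm,
        altloc = "", occ = 1, x = xyz[1], y = xyz[2], z = xyz[3],
        b = max(bi, 0.01), element = substr(nm, 1, 1),
        stringsAsFactors = FALSE)
    }
  }
  model <- do.call(rbind, atoms)
  model$is_h <- FALSE
  class(model) <- c("structure_model", "data.frame")
  list(data = model,
       truth = list(assay_kind = spec$assay_kind, seed = spec$seed,
                    n_res = n_res, b = b, sigma = spec$noise$sigma))
}

#' Write a generated dataset to disk (CSV/PDB + truth sidecar)
#'
#' Materializes [generate()] output in the pipeline's input schemas:
#' tabular kinds as CSV, kinetics as the kinetics CSV schema, structure
#' fixtures as PDB, with ground truth in `truth.json` alongside.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return paths of the files written, invisibly.
#' @export
write_synthetic <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  out <- generate(spec)
  paths <- character()
  kind <- spec$assay_kind
  if (kind %in% c("dose_response_hill", "saturation", "competition")) {
    p <- file.path(dir, paste0(kind, ".csv"))
    df <- as.data.frame(out$data)
    if (kind == "dose_response_hill") df$dose_unit <- "M"
    utils::write.csv(df, p, row.names = FALSE)
    paths <- p
  } else if (kind == "dose_response_operational") {
    p <- file.path(dir, paste0(kind, ".csv"))
    df <- do.call(rbind, lapply(out$data, function(cv) {
      data.frame(ligand = attr(cv, "ligand"), receptor = attr(cv, "receptor"),
                 pathway = attr(cv, "pathway"), dose = cv$dose,
                 dose_unit = "M", signal = cv$response,
                 replicate = cv$replicate, stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- p
  } else if (kind %in% c("kinetics_association", "kinetics_dissociation")) {
    p <- file.path(dir, paste0(kind, ".csv"))
    traces <- if (inherits(out$data, "kinetic_trace")) list(out$data) else out$data
    df <- do.call(rbind, lapply(traces, function(tr) {
      data.frame(trace_id = tr$trace_id, trace_type = tr$trace_type,
                 competitor = tr$competitor,
                 competitor_conc = tr$competitor_conc, conc_unit = "M",
                 time = tr$time, time_unit = "s", signal = tr$signal,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- p
  } else if (kind == "structure_fixture") {
    p <- file.path(dir, "structure_fixture_synthetic.pdb")
    write_structure_pdb(out$data, p)
    paths <- p
  }
  tp <- file.path(dir, "truth.json")
  jsonlite::write_json(out$truth, tp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, tp))
}

#' Packaged battery of study-design synthetic specs
#'
#' One spec per assay kind, with designs mirroring the study conditions
#' this package targets: catecholamine dose series over 1e-10..1e-4 M,
#' competition binding at 0.25 nM radioligand against a 0.080 nM-KD
#' site, association kinetics in the absence or presence of three
#' competitor concentrations, a two-pathway operational design with a
#' built-in pathway bias of ddlog(tau/KA) = 0.7, and a helix fixture
#' with a B-factor ramp. Parameter values are synthetic but plausible
#' for this assay family; default noise is 2% Gaussian.
#'
#' @param seed base seed; each spec gets a distinct derived seed.
#' @param sigma Gaussian noise, percent of the signal scale.
#' @return named list of [synthetic_spec()] objects.
#' @export
default_study_specs <- function(seed = 1L, sigma = 2) {
  noise <- list(model = "gaussian", sigma = sigma, type = "percent")
  list(
    dose_response_hill = synthetic_spec(
      "dose_response_hill",
      true_params = list(basal = 0, emax = 100, log_ec50 = -7.5, hill_n = 1),
      design = list(doses = lseq(1e-10, 1e-4, 8), replicates = 2L),
      noise = noise, seed = seed),
    dose_response_operational = synthetic_spec(
      "dose_response_operational",
      true_params = list(em = 100, trans_n = 1,
                         ligands = default_op_ligands()),
      design = list(doses = lseq(1e-10, 1e-4, 8)),
      noise = noise, seed = seed + 1L),
    saturation = synthetic_spec(
      "saturation",
      true_params = list(kd = 0.080e-9, bmax = 2.7),
      design = list(conc = lseq(0.01e-9, 1e-9, 8)),
      noise = noise, seed = seed + 2L),
    competition = synthetic_spec(
      "competition",
      true_params = list(ki = 3.5e-9, radioligand_conc = 0.25e-9,
                         radioligand_kd = 0.080e-9),
      design = list(conc = lseq(1e-11, 1e-5, 9), replicates = 3L),
      noise = noise, seed = seed + 3L),
    kinetics_association = synthetic_spec(
      "kinetics_association",
      true_params = list(k1 = 3e7, k2 = 3e-3, conc_l = 0.25e-9,
                         k3 = 1e6, k4 = 5e-3, bmax_scale = 100),
      design = list(competitor_concs = c(0, 3e-9, 10e-9, 30e-9),
                    t_grid = seq(60, 3600, length.out = 20)),
      noise = noise, seed = seed + 4L),
    kinetics_dissociation = synthetic_spec(
      "kinetics_dissociation",
      true_params = list(koff = 1e-3, y0 = 100, ns = 10),
      design = list(t_grid = seq(0, 3600, length.out = 20)),
      noise = noise, seed = seed + 5L),
    structure_fixture = synthetic_spec(
      "structure_fixture",
      design = list(n_res = 20L),
      noise = list(model = "gaussian", sigma = 0, type = "percent"),
      seed = seed + 6L)
  )
}
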