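# Experiment drivers: reproduce the three study designs end to end from a
# config (R list or YAML file) and write CSV/JSON results.

#' Build or read an experiment configuration
#'
#' @param experiment One of `"worked_example"` (sensed force of the
#'   exemplary vertical bundle under a vertical load ramp),
#'   `"flexion_compare"` (ground-truth model vs emulated simulator runs with
#'   a high and a low reference-configuration preload), `"pcl_sweep"`
#'   (gradual virtual PCL resection on both models).
#' @param out_dir Output directory.
#' @param seed Seed for fixture generation.
#' @param resolution Fixture mesh resolution (see [fixture_spec()]).
#' @param schedule Flexion schedule in degrees (steps <= 2).
#' @param preloads Two preloads (N) for `flexion_compare`
#'   (default `c(800, 100)`).
#' @param scales PCL stiffness scales for `pcl_sweep`
#'   (default `c(1, 0.5, 0.25, 0)`).
#' @param friction_mu Contact friction coefficient.
#' @param compliance Logical: apply the compliance curve in emulator runs.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("worked_example",
                                             "flexion_compare", "pcl_sweep"),
                              out_dir = tempfile("ligsim_"), seed = 1L,
                              resolution = 16, schedule = seq(0, 80, by = 2),
                              preloads = c(800, 100),
                              scales = c(1, 0.5, 0.25, 0),
                              friction_mu = 0.04, compliance = TRUE) {
  experiment <- match.arg(experiment)
  structure(list(experiment = experiment, out_dir = out_dir,
                 seed = as.integer(seed), resolution = resolution,
                 schedule = schedule, preloads = preloads, scales = scales,
                 friction_mu = friction_mu, compliance = compliance),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @param path YAML file with the fields above.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw), names(formals(experiment_config)))]
  if (!is.null(args$schedule)) args$schedule <- unlist(args$schedule)
  if (!is.null(args$preloads)) args$preloads <- unlist(args$preloads)
  if (!is.null(args$scales)) args$scales <- unlist(args$scales)
  do.call(experiment_config, args)
}

# Shared setup: fixtures, reference pose, reference configurations.
.experiment_setup <- function(config) {
  spec <- fixture_spec(resolution = config$resolution, seed = config$seed)
  surfaces <- make_implant_surfaces(spec)
  apparatus <- make_ligament_set(seed = config$seed, jitter = spec$jitter)
  law <- contact_law(friction_mu = config$friction_mu)
  curve <- do.call(compliance_curve, default_compliance_anchors())
  ref <- find_reference_pose(apparatus, surfaces, law)
  list(spec = spec, surfaces = surfaces, apparatus = apparatus, law = law,
       curve = curve, reference_pose = ref$pose)
}

#' Run an experiment end to end
#'
#' Generates the synthetic fixtures, runs the configured experiment and
#' writes per-run CSVs plus a `summary.json` (schema in
#' `system.file("schema", "experiment-summary-schema.json", package =
#' "ligsim")`). Identical configs reproduce byte-identical CSVs.
#'
#' @param config An [experiment_config()], or a path to a YAML config.
#' @return The summary list, invisibly; files under `config$out_dir`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- switch(config$experiment,
                    worked_example = .exp_worked_example(config),
                    flexion_compare = .exp_flexion_compare(config),
                    pcl_sweep = .exp_pcl_sweep(config))
  summary$experiment <- config$experiment
  summary$seed <- config$seed
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

.exp_worked_example <- function(config) {
  curve <- do.call(compliance_curve, default_compliance_anchors())
  bundle <- make_exemplary_lcl_fixture()
  tab <- worked_example_force_vs_load(bundle, curve)
  write.csv(tab, file.path(config$out_dir, "worked_example.csv"),
            row.names = FALSE)
  f0 <- force_from_strain(bundle$reference_strain, bundle$stiffness_k,
                          bundle$linear_limit)
  fmax <- tab$force_N[tab$load_N == 3000]
  list(quantities = list(
    force_at_reference_N = f0,
    force_at_3000N_N = fmax,
    relative_change_pct = 100 * (fmax - f0) / f0,
    displacement_at_500N_mm = displacement_at_load(curve, 500),
    displacement_at_3000N_mm = displacement_at_load(curve, 3000),
    linear_gradient_mm_per_1000N = 1000 * curve$linear_slope))
}

.exp_flexion_compare <- function(config) {
  setup <- .experiment_setup(config)
  curve <- if (config$compliance) setup$curve else NULL
  runs <- list(
    reference_model = {
      rc <- set_reference_configuration(setup$reference_pose, 0, NULL,
                                        setup$apparatus)
      run_reference_flexion(config$schedule, rc, setup$surfaces, setup$law)
    })
  for (p in config$preloads) {
    rc <- set_reference_configuration(setup$reference_pose, p, curve,
                                      setup$apparatus)
    proto <- flexion_protocol(config$schedule, preload = p)
    runs[[sprintf("emulator_%gN", p)]] <-
      run_passive_flexion(proto, rc, setup$surfaces, setup$law, curve)
  }
  for (nm in names(runs))
    write_flexion_csv(runs[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")))
  ref <- runs$reference_model$steps
  dev <- lapply(names(runs)[-1], function(nm) {
    st <- runs[[nm]]$steps
    data.frame(flexion_deg = st$flexion_deg, run = nm,
               axial_dev_N = st$axial_force_N - ref$axial_force_N,
               axial_dev_pct = 100 * (st$axial_force_N - ref$axial_force_N) /
                 pmax(ref$axial_force_N, 1),
               ap_dev_mm = st$femoral_ap_mm - ref$femoral_ap_mm,
               ie_dev_deg = st$tibial_ie_deg - ref$tibial_ie_deg)
  })
  dev <- do.call(rbind, dev)
  write.csv(dev, file.path(config$out_dir, "deviation_table.csv"),
            row.names = FALSE)
  a0 <- vapply(runs, function(r) r$steps$axial_force_N[1], 0)
  list(quantities = list(
    axial_force_at_0deg_N = as.list(a0),
    axial_force_mean_reference_N = mean(ref$axial_force_N),
    max_abs_axial_deviation_N = max(abs(dev$axial_dev_N))))
}

.exp_pcl_sweep <- function(config) {
  setup <- .experiment_setup(config)
  rc <- set_reference_configuration(setup$reference_pose, config$preloads[1],
                                    setup$curve, setup$apparatus)
  out <- list()
  for (model in c("reference_model", "emulator")) {
    curve <- if (model == "emulator") setup$curve else NULL
    sweep <- run_pcl_sweep(config$schedule, rc, setup$surfaces, setup$law,
                           scales = config$scales,
                           compliance_curve = curve)
    for (nm in names(sweep))
      write_flexion_csv(sweep[[nm]],
                        file.path(config$out_dir,
                                  sprintf("%s_%s.csv", model, nm)))
    last <- function(r, col) r$steps[[col]][nrow(r$steps)]
    full <- sweep[[1]]
    out[[model]] <- list(
      axial_force_80deg_N = as.list(vapply(sweep, last, 0, "axial_force_N")),
      femoral_ap_80deg_mm = as.list(vapply(sweep, last, 0, "femoral_ap_mm")),
      axial_force_diff_full_vs_resected_N =
        last(full, "axial_force_N") - last(sweep[[length(sweep)]], "axial_force_N"),
      femoral_ap_diff_full_vs_resected_mm =
        last(full, "femoral_ap_mm") - last(sweep[[length(sweep)]], "femoral_ap_mm"))
  }
  list(quantities = out)
}

#' Check an experiment summary against the bundled schema
#'
#' Light structural validation: required top-level keys and types per the
#' JSON schema shipped with the package.
#'
#' @param summary A summary list or a path to a `summary.json`.
#' @return `TRUE` invisibly, or an error describing the mismatch.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary)
  required <- c("quantities", "experiment", "seed")
  missing <- setdiff(required, names(summary))
  if (length(missing))
    stop("summary missing required field(s): ", paste(missing, collapse = ", "))
  if (!summary$experiment %in% c("worked_example", "flexion_compare",
                                 "pcl_sweep"))
    stop("unknown experiment id: ", summary$experiment)
  if (!is.list(summary$quantities)) stop("'quantities' must be an object")
  invisible(TRUE)
}
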