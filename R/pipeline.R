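#' Run manifest for an end-to-end experiment
#'
#' Describes one subject's run: where artifacts live, which registration
#' method to use, how many fractions to simulate, the working grid, and
#' the seed.  The phantom stage generates a planning anatomy plus
#' `n_fractions` daily anatomies with known deformations; later stages
#' consume only the files recorded here.
#'
#' @param out_dir Directory for all artifacts (created if needed).
#' @param method `"ffd"`, `"sc"`, `"msk"` or `"sc_msk"`.
#' @param subject_id Subject identifier.
#' @param n_fractions Number of daily fractions.
#' @param seed Seed for phantom generation and training.
#' @param shape,spacing_mm Working grid (network methods need dimensions
#'   divisible by 16).
#' @param prescription_gy Planning prescription dose.
#' @param net,ffd Optional parameter overrides (lists passed on to
#'   [regnet_config()] / [ffd_config()]).
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(out_dir, method = c("msk", "sc", "sc_msk", "ffd"),
                         subject_id = "phantom01", n_fractions = 3,
                         seed = 1, shape = c(32, 32, 16),
                         spacing_mm = c(6, 6, 6), prescription_gy = 80,
                         net = list(), ffd = list()) {
  method <- match.arg(method)
  structure(list(out_dir = out_dir, method = method,
                 subject_id = subject_id,
                 n_fractions = as.integer(n_fractions),
                 seed = as.integer(seed), shape = as.integer(shape),
                 spacing = as.numeric(spacing_mm),
                 prescription = prescription_gy,
                 net = net, ffd = ffd), class = "run_manifest")
}

manifest_paths <- function(m) {
  od <- m$out_dir
  k <- seq_len(m$n_fractions)
  list(
    planning_ct = file.path(od, "planning_ct.nii.gz"),
    planning_labels = file.path(od, "planning_labels.nii.gz"),
    planning_dose = file.path(od, "planning_dose.nii.gz"),
    fraction_ct = file.path(od, sprintf("fraction_%02d_ct.nii.gz", k)),
    fraction_labels = file.path(od, sprintf("fraction_%02d_labels.nii.gz", k)),
    true_field = file.path(od, sprintf("fraction_%02d_true_field.nii.gz", k)),
    dvf = file.path(od, sprintf("fraction_%02d_dvf.nii.gz", k)),
    metrics = file.path(od, "metrics.csv"),
    accum = file.path(od, "accumulated_dose.nii.gz"),
    dvh = file.path(od, "dvh.csv"),
    summary = file.path(od, "summary.json"))
}

require_stage <- function(paths, stage) {
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing artifact(s) ", paste(basename(missing), collapse = ", "),
         ": run stage '", stage, "' first")
}

#' Run the end-to-end pipeline on a phantom subject
#'
#' Orchestrates phantom generation, deformable registration with the
#' chosen method, geometric evaluation, dose accumulation, and reporting.
#' Every stage reads and writes only the files named by the manifest, so
#' stages can be re-run independently; a rerun with identical inputs and
#' seed reproduces identical outputs.
#'
#' @param manifest A [run_manifest()].
#' @param stages Subset of `c("phantom", "register", "evaluate",
#'   "accumulate", "report")`.
#' @return Invisibly, a list with the report `summary`, the `metrics` and
#'   `dvh` tables (for the stages that ran).
#' @export
run_pipeline <- function(manifest,
                         stages = c("phantom", "register", "evaluate",
                                    "accumulate", "report")) {
  stopifnot(inherits(manifest, "run_manifest"))
  stages <- match.arg(stages, several.ok = TRUE)
  p <- manifest_paths(manifest)
  dir.create(manifest$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- list()

  if ("phantom" %in% stages) {
    base <- phantom_spec(shape = manifest$shape,
                         spacing_mm = manifest$spacing)
    pairs <- phantom_cohort(manifest$n_fractions, seed = manifest$seed,
                            base_spec = base)
    write_volume(pairs[[1]]$planning$image, p$planning_ct)
    write_volume(pairs[[1]]$planning$labels, p$planning_labels)
    dose <- make_planning_dose(pairs[[1]],
                               prescription = manifest$prescription)
    write_volume(dose, p$planning_dose)
    for (k in seq_len(manifest$n_fractions)) {
      write_volume(pairs[[k]]$daily$image, p$fraction_ct[k])
      write_volume(pairs[[k]]$daily$labels, p$fraction_labels[k])
      write_volume(pairs[[k]]$field, p$true_field[k])
    }
  }

  if ("register" %in% stages) {
    require_stage(c(p$planning_ct, p$planning_labels, p$fraction_ct,
                    p$fraction_labels), "phantom")
    fixed <- clip_normalize(read_volume(p$planning_ct,
                                        frame_id = "planning"))
    fixed_lab <- read_volume(p$planning_labels, "label", "planning")
    movings <- lapply(p$fraction_ct, function(f)
      clip_normalize(read_volume(f, frame_id = "fraction")))
    moving_labs <- lapply(p$fraction_labels, read_volume, kind = "label",
                          frame_id = "fraction")
    if (manifest$method == "ffd") {
      cfg <- do.call(ffd_config, c(list(seed = manifest$seed),
                                   manifest$ffd))
      for (k in seq_len(manifest$n_fractions)) {
        f <- ffd_register(fixed, movings[[k]], cfg)
        write_volume(f, p$dvf[k])
      }
    } else {
      net_args <- utils::modifyList(
        list(variant = manifest$method, enc = c(8, 16, 16, 16), refine = 8,
             epochs = 5, seed = manifest$seed), manifest$net)
      cfg <- do.call(regnet_config, net_args)
      pairs <- lapply(seq_len(manifest$n_fractions), function(k)
        list(fixed = fixed, moving = movings[[k]],
             fixed_labels = fixed_lab, moving_labels = moving_labs[[k]]))
      fit <- train_network(cfg, pairs, val = pairs[1])
      for (k in seq_len(manifest$n_fractions)) {
        f <- predict_field(fit$net, fixed, movings[[k]], fixed_lab,
                           moving_labs[[k]])
        write_volume(f, p$dvf[k])
      }
    }
  }

  if ("evaluate" %in% stages) {
    require_stage(c(p$planning_labels, p$fraction_labels), "phantom")
    require_stage(p$dvf, "register")
    fixed_lab <- read_volume(p$planning_labels, "label", "planning")
    rows <- NULL
    for (k in seq_len(manifest$n_fractions)) {
      field <- read_field(p$dvf[k], frame_id = "planning")
      mlab <- read_volume(p$fraction_labels[k], "label", "fraction")
      wl <- warp(mlab, field)
      sm <- structure_metrics(fixed_lab, wl, field)
      sm$fraction <- k
      rows <- rbind(rows, sm)
    }
    utils::write.csv(rows, p$metrics, row.names = FALSE)
    out$metrics <- rows
  }

  if ("accumulate" %in% stages) {
    require_stage(p$planning_dose, "phantom")
    require_stage(p$dvf, "register")
    pdose <- read_volume(p$planning_dose, frame_id = "planning")
    fields <- lapply(p$dvf, read_field, frame_id = "planning")
    # fraction doses: planning dose carried rigidly (identity here — the
    # phantom fractions share the planning frame after rigid alignment)
    fds <- lapply(seq_len(manifest$n_fractions), function(k)
      fraction_dose(pdose, rigid_identity(),
                    frame_id = sprintf("fraction_%02d", k)))
    acc <- accumulate_dose(fds, fields, manifest$n_fractions)
    write_volume(acc$dose, p$accum)
    lab <- read_volume(p$planning_labels, "label", "planning")
    planning_total <- pdose
    planning_total$data <- planning_total$data * manifest$n_fractions
    tab_p <- dvh_indices(planning_total, lab)
    tab_a <- dvh_indices(acc$dose, lab)
    tab_p$dose <- "planning"; tab_a$dose <- "accumulated"
    dvh_tab <- rbind(tab_p, tab_a)
    utils::write.csv(dvh_tab, p$dvh, row.names = FALSE)
    out$dvh <- dvh_tab
  }

  if ("report" %in% stages) {
    require_stage(c(p$metrics, p$dvh), "evaluate")
    metrics <- utils::read.csv(p$metrics)
    dvh_tab <- utils::read.csv(p$dvh)
    tp <- dvh_tab[dvh_tab$dose == "planning", ]
    ta <- dvh_tab[dvh_tab$dose == "accumulated", ]
    diff_tab <- dose_report(tp[setdiff(names(tp), "dose")],
                            ta[setdiff(names(ta), "dose")])
    summary <- list(
      subject = manifest$subject_id,
      method = manifest$method,
      seed = manifest$seed,
      n_fractions = manifest$n_fractions,
      mean_dsc = round(mean(metrics$dsc), 6),
      per_organ_dsc = stats::setNames(
        round(tapply(metrics$dsc, metrics$structure, mean), 6),
        sort(unique(metrics$structure))),
      mean_fold_pct = round(mean(metrics$fold_pct), 6),
      dvh_diff = stats::setNames(round(diff_tab$dDmean_Gy, 6),
                                 diff_tab$structure))
    json <- jsonlite::toJSON(summary, auto_unbox = TRUE, pretty = TRUE,
                             digits = NA)
    writeLines(json, p$summary)
    out$summary <- summary
  }
  invisible(out)
}

#' Compare method reports
#'
#' Binds per-method pipeline results into one long table of per-fraction,
#' per-organ metric values — the raw material for method comparison (no
#' hypothesis testing is performed).
#'
#' @param reports Named list of results from [run_pipeline()] (at least
#'   two), run on identical subjects/fractions.
#' @return Long data frame with columns `method`, `fraction`, `structure`,
#'   `metric`, `value`.
#' @export
compare_methods <- function(reports) {
  if (length(reports) < 2) stop("input error: need at least two reports")
  if (is.null(names(reports)) || any(names(reports) == ""))
    stop("input error: reports must be named by method")
  key <- NULL
  rows <- NULL
  for (m in names(reports)) {
    met <- reports[[m]]$metrics
    if (is.null(met)) stop("input error: report '", m, "' has no metrics")
    k <- paste(sort(unique(paste(met$fraction, met$structure))),
               collapse = ";")
    if (is.null(key)) key <- k
    else if (!identical(key, k))
      stop("input error: reports cover different subjects/fractions")
    for (col in c("dsc", "asd_mm", "hd_mm", "hd95_mm", "fold_pct")) {
      rows <- rbind(rows, data.frame(
        method = m, fraction = met$fraction, structure = met$structure,
        metric = col, value = met[[col]]))
    }
  }
  rows
}
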