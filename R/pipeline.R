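#' Run one scenario end to end
#'
#' Builds the scene mesh for the configured layout and ECM variant, runs
#' the two-step solution, recovers the stress field and reduces it to a
#' per-component summary.
#'
#' @param cfg configuration list (see [default_config()]); `scene$layout`
#'   and `materials$ecm_variant` select the scenario.
#' @param mesh optional pre-built mesh (geometry is identical for stiff and
#'   soft variants of a layout, so the caller may reuse it).
#' @return list with `mesh`, `history`, `field`, `summary`, `config`.
#' @export
run_scenario <- function(cfg, mesh = NULL) {
  validate_config(cfg)
  if (is.null(mesh)) mesh <- build_scene(config_to_scene(cfg))
  mesh$meta$ecm_variant <- cfg$materials$ecm_variant
  mats <- config_to_materials(cfg)
  hist <- run_two_step_solution(mesh, mats,
                                pressure = cfg$load$pressure_pa,
                                config = config_to_solver(cfg))
  field <- recover_stress_field(mesh, mats, hist)
  summ <- summarize_component_stress(
    field, mesh, scenario = paste0(cfg$scene$layout, "_",
                                   cfg$materials$ecm_variant))
  list(mesh = mesh, history = hist, field = field, summary = summ,
       config = cfg)
}

#' Run the full 2 x 2 scenario matrix
#'
#' Runs {single cell, cell group} x {stiff ECM, soft ECM} with identical
#' geometry within each layout (only the ECM modulus differs), then
#' evaluates the stiff-vs-soft and group-vs-single ordering checks. A
#' non-convergent scenario is recorded as incomplete rather than
#' fabricating orderings. Fully deterministic for a given configuration.
#'
#' @param cfg base configuration; its `scene$layout` and
#'   `materials$ecm_variant` entries are overridden by the matrix.
#' @param keep_fields if `FALSE` (default) the per-element fields and
#'   meshes are dropped from the return value to save memory; summaries
#'   and provenance are always kept.
#' @return object of class `cytofem_report`: `scenarios` (named list),
#'   `summaries`, `comparison` (or `NULL` if incomplete), `incomplete`,
#'   `provenance`.
#' @export
run_scenario_matrix <- function(cfg = default_config(), keep_fields = FALSE) {
  validate_config(cfg)
  scenarios <- list()
  incomplete <- character()
  counts <- list()
  iters <- integer()
  for (layout in c("single", "group")) {
    cfg_l <- cfg
    cfg_l$scene$layout <- layout
    mesh <- build_scene(config_to_scene(cfg_l))
    counts[[layout]] <- c(nodes = nrow(mesh$nodes), tets = nrow(mesh$tets),
                          tris = nrow(mesh$tris), bars = nrow(mesh$bars))
    for (variant in c("stiff", "soft")) {
      id <- paste0(layout, "_", variant)
      cfg_s <- cfg_l
      cfg_s$materials$ecm_variant <- variant
      res <- tryCatch(run_scenario(cfg_s, mesh = mesh),
                      error = function(e) e)
      if (inherits(res, "error")) {
        incomplete <- c(incomplete, id)
        scenarios[[id]] <- list(error = conditionMessage(res))
      } else {
        iters[id] <- sum(vapply(res$history$increments,
                                function(i) i$iterations, 1L))
        if (!keep_fields) {
          res$mesh <- NULL
          res$field <- NULL
          res$history$increments <- NULL
        }
        scenarios[[id]] <- res
      }
    }
  }
  summaries <- lapply(scenarios[!names(scenarios) %in% incomplete],
                      function(sc) sc$summary)
  comparison <- if (length(incomplete)) NULL else
    compare_scenarios(unname(summaries))
  cfg_file <- tempfile(fileext = ".yaml")
  save_config(cfg, cfg_file)
  hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  structure(list(scenarios = scenarios, summaries = summaries,
                 comparison = comparison, incomplete = incomplete,
                 provenance = list(config = cfg, config_md5 = hash,
                                   element_counts = counts,
                                   newton_iterations = iters)),
            class = "cytofem_report")
}

#' @export
print.cytofem_report <- function(x, ...) {
  cat("cytofem scenario report (config md5", x$provenance$config_md5, ")\n")
  if (length(x$incomplete))
    cat("  INCOMPLETE scenarios:", paste(x$incomplete, collapse = ", "), "\n")
  for (s in x$summaries) print(s)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Export a scenario report to CSV tables and a text report
#'
#' Writes the per-component maximum-HMH tables (ECM, cortex, cytoplasm,
#' nuclear membrane, nucleus: rows are scene layouts, columns stiff/soft),
#' the uniaxial-stress extreme table, the ordering-check table, and a
#' human-readable text report. Numbers are written with full precision so
#' a re-read reproduces them exactly; output is byte-deterministic.
#' An incomplete report is exported with explicit "incomplete" markers.
#'
#' @param report a `cytofem_report`.
#' @param dir output directory (created if missing).
#' @param formats subset of `c("csv", "txt", "vtu")`; `"vtu"` writes the
#'   per-scenario stress fields and requires a report produced with
#'   `keep_fields = TRUE`.
#' @return invisibly, the paths written.
#' @export
export_report <- function(report, dir, formats = c("csv", "txt")) {
  stopifnot(inherits(report, "cytofem_report"))
  if (!length(report$summaries))
    stop("export refused: report contains no completed scenarios")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  get_val <- function(layout, variant, fn) {
    id <- paste0(layout, "_", variant)
    if (!id %in% names(report$summaries)) return(NA_real_)
    fn(report$summaries[[id]])
  }
  layouts <- unique(sub("_(stiff|soft)$", "", names(report$summaries)))
  layout_label <- function(ly) {
    id <- paste0(ly, "_", c("stiff", "soft"))
    id <- id[id %in% names(report$summaries)][1]
    n <- report$summaries[[id]]$n_cells
    sprintf("%d cell%s", n, if (n > 1) "s" else "")
  }
  if ("csv" %in% formats) {
    comp_tbl <- function(comp) {
      data.frame(
        case = vapply(layouts, layout_label, ""),
        stiff_ecm_pa = fmt_num(vapply(layouts, get_val, 1, variant = "stiff",
          fn = function(s) s$component_max[[comp]])),
        soft_ecm_pa = fmt_num(vapply(layouts, get_val, 1, variant = "soft",
          fn = function(s) s$component_max[[comp]])),
        row.names = NULL, stringsAsFactors = FALSE)
    }
    tables <- list(ecm = "ECM", cortex = "cortex", cytoplasm = "cytoplasm",
                   nuclear_membrane = "nuclear_membrane",
                   nucleus = "nucleus")
    for (nm in names(tables)) {
      p <- file.path(dir, paste0("max_hmh_", nm, ".csv"))
      write.csv(comp_tbl(tables[[nm]]), p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
    uni <- data.frame(
      case = vapply(layouts, layout_label, ""),
      s11_max_stiff_pa = fmt_num(vapply(layouts, get_val, 1,
        variant = "stiff", fn = function(s) s$s11_max)),
      s11_min_stiff_pa = fmt_num(vapply(layouts, get_val, 1,
        variant = "stiff", fn = function(s) s$s11_min)),
      s11_max_soft_pa = fmt_num(vapply(layouts, get_val, 1,
        variant = "soft", fn = function(s) s$s11_max)),
      s11_min_soft_pa = fmt_num(vapply(layouts, get_val, 1,
        variant = "soft", fn = function(s) s$s11_min)),
      row.names = NULL, stringsAsFactors = FALSE)
    p <- file.path(dir, "uniaxial_s11.csv")
    write.csv(uni, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
    if (!is.null(report$comparison)) {
      ck <- report$comparison$checks
      for (col in c("value_larger", "value_smaller", "ratio"))
        ck[[col]] <- fmt_num(ck[[col]])
      p <- file.path(dir, "ordering_checks.csv")
      write.csv(ck, p, row.names = FALSE, quote = FALSE)
      paths <- c(paths, p)
    }
  }
  if ("vtu" %in% formats) {
    for (id in setdiff(names(report$scenarios), report$incomplete)) {
      sc <- report$scenarios[[id]]
      if (is.null(sc$mesh) || is.null(sc$field))
        stop("export error: VTU output needs a report built with ",
             "keep_fields = TRUE")
      p <- file.path(dir, paste0(id, ".vtu"))
      write_vtu(sc$mesh, p, field = sc$field)
      paths <- c(paths, p)
    }
  }
  if ("txt" %in% formats) {
    p <- file.path(dir, "report.txt")
    con <- file(p, "w")
    sink(con)
    on.exit({ sink(); close(con) }, add = TRUE)
    cat("cytofem scenario report\n")
    cat("config md5:", report$provenance$config_md5, "\n")
    if (length(report$incomplete))
      cat("INCOMPLETE scenarios:",
          paste(report$incomplete, collapse = ", "), "\n")
    for (s in report$summaries) print(s)
    if (!is.null(report$comparison)) print(report$comparison)
    paths <- c(paths, p)
  }
  invisible(paths)
}
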