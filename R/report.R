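#' Run the binding workflow for one or more conditions
#'
#' For each condition, fits every per-temperature titration, then runs the
#' van't Hoff analysis and assembles a thermodynamic summary row (mean Ka,
#' mean Hill coefficient, dH, mean TdS and dG). A condition with a single
#' temperature yields a binding row without thermodynamic parameters (with
#' a warning).
#'
#' @param conditions Named list; each element is either a list of
#'   [titration_series()] objects (one per temperature) or a list of
#'   `c(csv, yaml)` path pairs readable by [read_titration()].
#' @param stock_conc Titrant stock concentration (mol/L), or NULL to use
#'   the per-spectrum ligand concentrations on record.
#' @param metric Intensity metric, see [spectrum_intensity()].
#' @param units Energy unit system.
#' @return A list (class `binding_section`) with one `thermo_result` per
#'   condition plus the underlying per-temperature `hill_fit`s.
#' @export
run_binding <- function(conditions, stock_conc = NULL, metric = "peak",
                        units = "kcal") {
  out <- lapply(names(conditions), function(lab) {
    entries <- conditions[[lab]]
    series <- lapply(entries, function(e) {
      if (inherits(e, "titration_series")) e
      else read_titration(e[[1]], e[[2]])
    })
    fits <- lapply(series, function(s)
      tryCatch(fit_titration(s, stock_conc = stock_conc, metric = metric),
               error = function(err)
                 stop("condition '", lab, "': ", conditionMessage(err))))
    summary <- condition_summary(fits, units = units, label = lab)
    list(summary = summary, fits = fits)
  })
  names(out) <- names(conditions)
  structure(out, class = "binding_section")
}

#' Run the STD epitope workflow
#'
#' Builds one normalized epitope map per condition and, when at least two
#' conditions are present, a pairwise comparison of the first two
#' (per-proton differences, counts above the saturation threshold, rank
#' concordance). Conditions with mismatched proton labels are compared on
#' the shared subset with a warning.
#'
#' @param tables Named list; each element a peak data.frame (or a CSV path
#'   readable by [read_std_table()]).
#' @param threshold Percentage threshold for the strong-transfer count.
#' @return A list (class `epitope_section`) with `maps` and, when
#'   applicable, `comparison`.
#' @export
run_epitope <- function(tables, threshold = 90) {
  maps <- lapply(names(tables), function(lab) {
    t <- tables[[lab]]
    if (is.character(t)) t <- read_std_table(t)
    epitope_from_peaks(t, condition = lab)
  })
  names(maps) <- names(tables)
  out <- list(maps = maps)
  if (length(maps) >= 2L) {
    a <- maps[[1]]; b <- maps[[2]]
    if (!setequal(a$label, b$label))
      warning("proton labels differ between conditions; comparing the intersection")
    out$comparison <- compare_epitopes(a, b, threshold = threshold)
  }
  structure(out, class = "epitope_section")
}

#' Assemble and write a study report
#'
#' Serializes analysis sections into one machine-readable JSON plus
#' per-section CSV tables and a Markdown summary, with a provenance block
#' (package version, seed, config hash). Identical inputs give
#' byte-identical JSON.
#'
#' @param sections Named list of sections from [run_binding()],
#'   [run_epitope()], [analyze_trace()], [contact_residues()] or plain
#'   lists.
#' @param out_dir Output directory (created if missing).
#' @param seed Seed recorded in the provenance block.
#' @return Invisibly, the path of the JSON report.
#' @export
run_report <- function(sections, out_dir, seed = NA) {
  if (length(sections) == 0L) stop("no sections to report")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  payload <- lapply(sections, .section_payload)
  cfg_json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  report <- list(
    provenance = list(tool = "ligbind",
                      version = as.character(utils::packageVersion("ligbind")),
                      seed = seed,
                      config_hash = unname(tools::md5sum(tmp))),
    sections = payload)
  unlink(tmp)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  md <- c("# Binding study report", "",
          sprintf("Sections: %s", paste(names(sections), collapse = ", ")),
          sprintf("Config hash: %s", report$provenance$config_hash))
  for (nm in names(sections)) {
    sec <- sections[[nm]]
    if (inherits(sec, "binding_section")) {
      rows <- do.call(rbind, lapply(sec, function(cond) {
        s <- cond$summary
        data.frame(condition = s$label %||% NA, mean_ka = s$mean_ka,
                   mean_n = s$mean_n, delta_h = s$delta_h %||% NA,
                   mean_t_delta_s = s$mean_t_delta_s %||% NA,
                   mean_delta_g = s$mean_delta_g %||% NA)
      }))
      utils::write.csv(rows, file.path(out_dir, paste0(nm, "_summary.csv")),
                       row.names = FALSE)
      md <- c(md, "", sprintf("## %s", nm),
              utils::capture.output(print(rows, row.names = FALSE)))
    }
    if (inherits(sec, "epitope_section")) {
      for (cond in names(sec$maps)) {
        utils::write.csv(as.data.frame(sec$maps[[cond]]),
                         file.path(out_dir,
                                   paste0(nm, "_", gsub("\\W+", "_", cond),
                                          ".csv")),
                         row.names = FALSE)
      }
    }
  }
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(json_path)
}

# Flatten a section into JSON-serializable primitives.
.section_payload <- function(sec) {
  if (inherits(sec, "binding_section")) {
    lapply(sec, function(cond) {
      s <- cond$summary
      list(condition = s$label, mean_ka = s$mean_ka, sd_ka = s$sd_ka,
           mean_n = s$mean_n, sd_n = s$sd_n,
           delta_h = s$delta_h, delta_s = s$delta_s,
           t_delta_s = s$t_delta_s, delta_g = s$delta_g,
           mean_t_delta_s = s$mean_t_delta_s,
           mean_delta_g = s$mean_delta_g,
           temperatures = s$temperatures, ka = s$ka, n = s$n)
    })
  } else if (inherits(sec, "epitope_section")) {
    res <- list(maps = lapply(sec$maps, function(m)
      list(condition = attr(m, "condition"),
           label = m$label, chemical_shift = m$chemical_shift,
           raw = m$raw, pct = m$pct)))
    if (!is.null(sec$comparison))
      res$comparison <- list(
        table = sec$comparison$table,
        count_a = sec$comparison$count_a,
        count_b = sec$comparison$count_b,
        threshold = sec$comparison$threshold,
        rank_concordance = sec$comparison$rank_concordance)
    res
  } else if (inherits(sec, "hydro_result")) {
    list(d_h_nm = sec$d_h_nm, diffusion = sec$diffusion, gamma = sec$gamma,
         q = sec$q, fit_quality = sec$fit_quality)
  } else if (inherits(sec, "contact_report")) {
    list(cutoff = attr(sec, "cutoff"), residues = as.data.frame(sec))
  } else {
    sec
  }
}
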