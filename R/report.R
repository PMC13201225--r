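## Per-vessel report layer: executes every measurement stage on a final
## label volume (plus optional intensity volume) and collects the
## quantities of interest into CSV/JSON-ready tables.

#' Run every measurement stage on a vessel and collect a report
#'
#' Executes PC coverage, surface-domain thickness, ELP volume per area,
#' peg metrics and counts by type, peg edge-distance cumulative values,
#' EC-nucleus peg proximity, PC-ER contact statistics by surface category,
#' and (when an intensity volume is supplied) the interface-skeleton ELP
#' fractions. Stage failures are caught and recorded in the failure
#' manifest; the report is then partial. Given fixed inputs and
#' configuration the report is deterministic.
#'
#' @param vol A final [LabelVolume-class].
#' @param img Optional co-registered [IntensityVolume-class].
#' @param soma_mask Optional logical array (PC soma); when missing and a PC
#'   nucleus exists, [somaMaskFromNucleus] is used.
#' @param pegs Optional [PegSet-class]; rebuilt from peg classes if absent.
#' @param outdir Optional directory: CSV tables and a JSON summary are
#'   written there.
#' @param config Named list of stage options (`coverage_radius_nm`,
#'   `elp_threshold`, `bin_um`, `contact_tol_nm`, `soma_radius_nm`).
#' @return list of class `"VesselReport"`: `summary` (named numerics),
#'   `coverage`, `domains`, `elp_by_domain`, `pegs`, `peg_counts`,
#'   `edge_distances`, `nucleus_proximity`, `er_contact`,
#'   `interface_elp`, `failures`, `provenance`.
#' @export
runReport <- function(vol, img = NULL, soma_mask = NULL, pegs = NULL,
                      outdir = NULL, config = list()) {
  stopifnot(is(vol, "LabelVolume"))
  cfg <- utils::modifyList(list(coverage_radius_nm = NA,
                                elp_threshold = 180, bin_um = 0.1,
                                contact_tol_nm = spacing(vol)@sx,
                                soma_radius_nm = 1000), config)
  failures <- character(0)
  res <- list()
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures <<- c(failures, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }
  g <- voxelData(vol)

  res$coverage <- step("coverage", {
    cp <- pcCoverage(vol, coverage_radius_nm = cfg$coverage_radius_nm)
    cp
  })
  if (is.null(soma_mask))
    soma_mask <- step("soma_mask", {
      if (any(g == 6L)) somaMaskFromNucleus(vol, cfg$soma_radius_nm)
      else array(FALSE, dim(g))
    })
  res$domains <- step("surface_domains", partitionSurface(vol, soma_mask))
  res$elp_by_domain <- step("elp_by_domain",
                            elpVolumePerArea(vol, res$domains, soma_mask))
  if (is.null(pegs)) pegs <- step("peg_set", .buildPegSet(vol))
  res$pegs <- if (!is.null(pegs)) pegTable(pegs) else NULL
  res$peg_counts <- if (!is.null(res$pegs)) {
    data.frame(peg_type = c("PC-EC", "EC-PC", "EC-EC"),
               n = c(sum(res$pegs$peg_type == "PC-EC"),
                     sum(res$pegs$peg_type == "EC-PC"),
                     sum(res$pegs$peg_type == "EC-EC")))
  } else NULL
  res$edge_distances <- step("edge_distances",
                             pegEdgeDistances(vol, pegs,
                                              bin_um = cfg$bin_um))
  res$nucleus_proximity <- step("nucleus_proximity",
                                pegNucleusProximity(vol, pegs,
                                                    cfg$contact_tol_nm))
  res$er_contact <- step("er_contact", {
    cats <- categorizePcSurface(vol)
    erContactStats(vol, cats, cfg$contact_tol_nm)
  })
  if (!is.null(img)) {
    res$interface_elp <- step("interface_elp", {
      sk <- interfaceSkeleton(vol)
      sk <- interfaceIntensity(sk, img, vol)
      elpFractionByDomain(sk, threshold = cfg$elp_threshold)
    })
  }

  cumAt <- function(ed, at) {
    if (is.null(ed)) return(NA_real_)
    i <- findInterval(at - 1e-9, ed$breaks_um)
    if (i < 1 || i > length(ed$observed_cum)) return(NA_real_)
    ed$observed_cum[i]
  }
  summary <- c(
    mean_coverage_percent = if (!is.null(res$coverage))
      res$coverage$mean_percent else NA_real_,
    n_pegs_pc_ec = if (!is.null(res$peg_counts)) res$peg_counts$n[1]
      else NA_real_,
    n_pegs_ec_pc = if (!is.null(res$peg_counts)) res$peg_counts$n[2]
      else NA_real_,
    n_pegs_ec_ec = if (!is.null(res$peg_counts)) res$peg_counts$n[3]
      else NA_real_,
    edge_cum_0_5_um = cumAt(res$edge_distances, 0.5),
    edge_cum_1_0_um = cumAt(res$edge_distances, 1.0),
    nucleus_contact_count = if (!is.null(res$nucleus_proximity))
      res$nucleus_proximity$contact_count else NA_real_)
  if (!is.null(res$domains)) {
    s <- res$domains$summary
    summary <- c(summary, stats::setNames(
      s$mean_thickness_nm, paste0("thickness_", s$domain, "_nm")))
  }
  if (!is.null(res$er_contact)) {
    summary <- c(summary, stats::setNames(
      res$er_contact$contact_percent,
      paste0("er_contact_", res$er_contact$category, "_pct")))
  }
  if (!is.null(res$interface_elp)) {
    summary <- c(summary, stats::setNames(
      res$interface_elp$percent,
      paste0("interface_elp_", res$interface_elp$domain, "_pct")))
  }
  res$summary <- summary
  res$failures <- failures
  res$provenance <- list(
    package = "vesselmorph3d",
    version = as.character(utils::packageVersion("vesselmorph3d")),
    config = cfg,
    volume_dim = dim(g),
    spacing_nm = as.numeric(spacing(vol)))
  class(res) <- "VesselReport"

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) if (!is.null(x))
      utils::write.csv(x, file.path(outdir, f), row.names = FALSE)
    if (!is.null(res$coverage))
      wr(res$coverage$per_slice, "coverage.csv")
    if (!is.null(res$domains))
      wr(res$domains$summary, "thickness_by_domain.csv")
    wr(res$elp_by_domain, "elp_by_domain.csv")
    wr(res$pegs, "pegs.csv")
    wr(res$peg_counts, "peg_counts.csv")
    if (!is.null(res$edge_distances)) {
      ed <- res$edge_distances
      wr(data.frame(bin_lo_um = utils::head(ed$breaks_um, -1),
                    bin_hi_um = ed$breaks_um[-1],
                    observed_prob = ed$observed_prob,
                    available_prob = ed$available_prob,
                    observed_cum = ed$observed_cum,
                    available_cum = ed$available_cum),
         "edge_distance_hist.csv")
    }
    wr(res$er_contact, "er_contact_by_category.csv")
    wr(res$interface_elp, "interface_elp_by_domain.csv")
    jsonlite::write_json(
      list(summary = as.list(summary), failures = failures,
           provenance = res$provenance),
      file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  res
}

#' @export
print.VesselReport <- function(x, ...) {
  cat("VesselReport\n")
  for (nm in names(x$summary))
    cat(sprintf("  %-28s %s\n", nm, format(x$summary[[nm]], digits = 5)))
  if (length(x$failures))
    cat("  failed stages:", paste(x$failures, collapse = "; "), "\n")
  invisible(x)
}
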