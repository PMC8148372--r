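#' @title Full-pipeline orchestration and export
#'
#' @description
#' [run_full_analysis()] runs the entire evaluation — short-term ledgers,
#' long-term incremental results for every subgroup and perspective, tornado
#' DSA, PSA and CEAC — and writes machine-readable CSV/JSON artifacts plus a
#' run manifest (input hash, seed, versions) sufficient to reproduce every
#' output. Monetary columns carry both SEK and EUR (SEK / 10.3); display
#' rounding follows the source conventions (whole SEK for ledgers, nearest
#' 100,000 SEK for long-term results) while the files keep full precision.
#'
#' @name reporting
NULL

#' Run the complete analysis pipeline
#'
#' @param config Parameter configuration (path, list or `NULL` for the
#'   packaged baseline), as in [load_parameters()].
#' @param out_dir Output directory; created if missing.
#' @param seed Master seed for the PSA.
#' @param psa_n Number of PSA draws (study value 5,000).
#' @param wtp_max Upper end of the CEAC willingness-to-pay grid, SEK.
#' @param figures Also write PNG figures (tornado, CE plane, CEAC)?
#' @return The manifest (list), invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_full_analysis <- function(config = NULL, out_dir = "bpscreen-results",
                              seed = 1L, psa_n = 5000, wtp_max = 3e6,
                              figures = FALSE) {
  params <- load_parameters(config)
  table <- default_life_table()
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir,
                  call. = FALSE)
  }
  w <- function(df, name) {
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  st <- short_term_analysis(params)
  led <- ledger_table(st)
  led$total_eur <- sek_to_eur(led$total, params$sek_per_eur)
  w(led, "short_term_ledgers.csv")
  pc <- do.call(rbind, lapply(names(st$per_case), function(pp) {
    x <- st$per_case[[pp]]
    data.frame(perspective = pp, delta_cost_sek = x$delta_cost,
               delta_cases = x$delta_cases,
               cost_per_case_sek = x$incremental_per_case,
               cost_per_case_eur = sek_to_eur(x$incremental_per_case,
                                              params$sek_per_eur))
  }))
  w(pc, "short_term_per_case.csv")

  ce <- run_cea(params, table)
  ce_out <- as.data.frame(ce)
  ce_out$d_cost_eur <- sek_to_eur(ce_out$d_cost, params$sek_per_eur)
  ce_out$icer_eur <- sek_to_eur(ce_out$icer, params$sek_per_eur)
  w(ce_out, "long_term_results.csv")

  dsa <- one_way_dsa(params, table)
  w(as.data.frame(dsa), "dsa_tornado.csv")

  draws <- run_psa(params, n = psa_n, seed = seed, table = table)
  w(as.data.frame(draws), "psa_draws.csv")
  cv <- ceac(draws, wtp = seq(0, wtp_max, by = 25000))
  w(as.data.frame(cv), "ceac.csv")

  if (figures) {
    gg_save <- function(p, name) {
      grDevices::png(file.path(out_dir, name), width = 1400, height = 1000,
                     res = 160)
      print(p)
      grDevices::dev.off()
    }
    gg_save(plot_tornado(dsa), "tornado.png")
    gg_save(plot_ce_plane(draws), "ce_plane.png")
    gg_save(plot_ceac(cv), "ceac.png")
  }

  cfg_hash <- if (is.character(config)) {
    unname(tools::md5sum(config))
  } else {
    "packaged-baseline"
  }
  manifest <- list(
    package = "bpscreen",
    version = as.character(utils::packageVersion("bpscreen")),
    r_version = R.version.string,
    config = cfg_hash, seed = seed, psa_n = psa_n, wtp_max = wtp_max,
    sek_per_eur = params$sek_per_eur,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
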