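#' Write a trajectory to CSV
#'
#' Plain CSV with header `mcs,layer,f_C,f_C_int,f_C_no`.
#'
#' @param traj trajectory data frame from [run_mcs()] or [run_duplex()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj[, c("mcs", "layer", "f_C", "f_C_int", "f_C_no")], path,
            row.names = FALSE)
  invisible(path)
}

#' Write a sweep result to CSV
#'
#' Long format, one row per replicate:
#' `rho,alpha,b,variant,replicate,mean_fC,sd_fC,absorbed`.
#'
#' @param sweep a `sweep_result` from [sweep_rho_alpha()] or [scan_b()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- c("rho", "alpha", "b", "variant", "replicate", "mean_fC", "sd_fC",
            "absorbed")
  write.csv(as.data.frame(sweep)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run without the original config
#' file: the fully resolved configuration, the master seed, the package
#' version, timestamps, and the paths of every output file the run produced.
#'
#' @param cfg the resolved [sim_config()]
#' @param outputs character vector of output file paths
#' @param path manifest file path
#' @param extra optional named list of additional fields (e.g. summaries,
#'   absorption flags)
#' @return `path`, invisibly
#' @export
write_manifest_json <- function(cfg, outputs, path, extra = list()) {
  manifest <- c(
    list(
      config = config_as_list(cfg),
      master_seed = cfg$seed,
      package = "duplexgames",
      version = as.character(utils::packageVersion("duplexgames")),
      written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      outputs = as.list(outputs)
    ),
    extra
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
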