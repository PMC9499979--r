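#' Build a scene specification from a configuration list or YAML file
#'
#' Translates a nested key-value description (typically read from a YAML
#' file) into a [scene_spec()]. Top-level keys mirror the `scene_spec`
#' arguments (`duration`, `sample_rate`, `noise_floor_db`, `seed`, `t0`,
#' `disk_write`); `events` is a list whose entries name a `template`
#' (`cuvier`, `delphinid`, `echosounder_28`, `echosounder_50`,
#' `ua_comb`, `vessel`), a `start` time, and either `count`/`ipi`
#' (pulsed sources) or `on_duration` (continuous sources). `level` and,
#' for the comb, `preset` override template defaults. (`count` rather
#' than `n` because an unquoted `n` is a YAML 1.1 boolean; a quoted
#' `"n"` key is also accepted.)
#'
#' @param config a nested list, or a path to a YAML file when `config`
#'   is a single string (requires the `yaml` package).
#' @return a [scene_spec()].
#' @export
scene_from_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$duration))
  mk_template <- function(ev) {
    lvl <- ev$level
    switch(ev$template,
      cuvier = if (is.null(lvl)) template_cuvier() else template_cuvier(level = lvl),
      delphinid = if (is.null(lvl)) template_delphinid() else template_delphinid(level = lvl),
      echosounder_28 = if (is.null(lvl)) template_echosounder("28")
        else template_echosounder("28", level = lvl),
      echosounder_50 = if (is.null(lvl)) template_echosounder("50")
        else template_echosounder("50", level = lvl),
      ua_comb = {
        preset <- if (is.null(ev$preset)) "anchored" else ev$preset
        if (is.null(lvl)) template_ua_comb(preset)
        else template_ua_comb(preset, level = lvl)
      },
      vessel = if (is.null(lvl)) template_vessel() else template_vessel(level = lvl),
      stop("unknown template kind: ", ev$template))
  }
  events <- lapply(config$events, function(ev) {
    tpl <- mk_template(ev)
    n_ev <- if (!is.null(ev$count)) ev$count else ev[["n"]]
    scene_event(tpl, start = ev$start,
                n = if (is.null(n_ev)) 1 else n_ev,
                ipi = if (is.null(ev$ipi)) NULL else as.numeric(ev$ipi),
                on_duration = ev$on_duration)
  })
  arg <- function(nm, default) if (is.null(config[[nm]])) default else config[[nm]]
  scene_spec(duration = config$duration,
             sample_rate = arg("sample_rate", 200000),
             events = events,
             noise_floor_db = arg("noise_floor_db", 40),
             seed = arg("seed", 1),
             t0 = arg("t0", as.POSIXct("2019-01-01 00:00:00", tz = "UTC")),
             full_scale_db = arg("full_scale_db", 140),
             disk_write = arg("disk_write", FALSE))
}
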