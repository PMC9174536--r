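# Run configuration: a nested key/value structure (YAML on disk) with one
# section per module, validated against the defaults so misspelled keys
# fail loudly before any side effect.

#' Default run configuration
#'
#' Sections: `preprocess` (enhancement strategy and its parameters; exactly
#' one of none/tophat/clahe is applied per run), `model` (the frozen network
#' layout, see [net_config()]), `train` (see [train_config()]), `loss` (see
#' [loss_params()]), `data` (split sizes), plus the global `seed` from which
#' per-module seeds are derived.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    preprocess = list(
      strategy = "none",          # one of none | tophat | clahe
      se_radius = 9L,             # top-hat disk radius at 300x300 scale
      clip_limit = 2.0,
      tiles = c(8L, 8L),
      crop = NULL,                # c(h, w) central crop, e.g. c(288, 288)
      resize = NULL               # c(h, w) test-time resize
    ),
    model = unclass(net_config()),
    train = train_config(),
    loss = loss_params(),
    data = list(train_count = NULL, test_count = NULL)
  )
}

# Validate `user` against template `def`, recursively; collect unknown keys.
merge_validate <- function(def, user, prefix = "") {
  bad <- character(0)
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(def)) {
      bad <- c(bad, full)
      next
    }
    dv <- def[[key]]; uv <- user[[key]]
    if (is.list(dv) && !is.null(names(dv)) && is.list(uv)) {
      sub <- merge_validate(dv, uv, paste0(full, "."))
      def[[key]] <- sub$value
      bad <- c(bad, sub$bad)
    } else {
      if (!is.null(dv) && !is.list(dv) && is.numeric(dv) && !is.numeric(uv) &&
          !is.logical(uv)) {
        stop("config key '", full, "' expects a numeric value, got: ",
             paste(uv, collapse = ", "))
      }
      def[[key]] <- uv
    }
  }
  list(value = def, bad = bad)
}

#' Parse and validate a run configuration
#'
#' Loads a YAML config file (if given), applies it over [default_config()],
#' then applies `overrides` (dotted keys such as `model.t`) on top --
#' overrides win.  Any unknown key, at any level, is an error that lists
#' every offending key.
#'
#' @param path Optional YAML file path; an empty or absent file yields the
#'   full default configuration.
#' @param overrides Named list of dotted-key overrides
#'   (e.g. `list("model.t" = 4)`).
#' @return The resolved configuration list.
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      res <- merge_validate(cfg, user)
      if (length(res$bad)) {
        stop("unknown config key(s): ", paste(res$bad, collapse = ", "))
      }
      cfg <- res$value
    }
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- cfg
    # verify the path exists
    for (d in seq_along(parts)) {
      if (!parts[d] %in% names(node)) {
        stop("unknown config key(s): ", key)
      }
      if (d < length(parts)) node <- node[[parts[d]]]
    }
    cfg[[parts]] <- overrides[[key]]
  }
  cfg
}

# Derive a per-module seed from the global seed by a fixed splitting rule.
derive_seed <- function(seed, module) {
  offs <- c(synth = 101L, split = 211L, init = 307L, train = 401L,
            augment = 503L)
  as.integer((as.numeric(seed) * 1009 + offs[[module]]) %% 2147483647)
}

# Apply the configured enhancement strategy to one gray image.
apply_preprocess <- function(img, pcfg) {
  if (!is.null(pcfg$crop)) img <- center_crop(img, pcfg$crop)
  switch(pcfg$strategy,
    none = img,
    tophat = tophat_enhance(img, structuring_element("disk",
                            scaled_se_radius(img, pcfg$se_radius))),
    clahe = clahe(img, pcfg$clip_limit, pcfg$tiles),
    stop("unknown preprocessing strategy: ", pcfg$strategy))
}
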