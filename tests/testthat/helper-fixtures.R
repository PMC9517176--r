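# Shared fixtures. The default city layout is fixed, so expensive pieces
# (parcels, roads, extraction) are built once per test file and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

tiny_config <- function(seed = 1) {
  city_config(
    extent = 12000,
    zone_counts = c(industrial = 6, educational = 6,
                    residential = 7, commercial = 6),
    n_sites = 6, n_months = 12, bg_cell = 1500,
    seed = seed
  )
}

tiny_city <- function() {
  cached("tiny_city", {
    cfg <- tiny_config()
    p <- generate_parcels(cfg)
    r <- generate_roads(cfg)
    list(cfg = cfg, parcels = p, roads = r,
         buildings = generate_buildings(cfg, p))
  })
}

default_city_static <- function() {
  cached("default_city_static", {
    cfg <- city_config(seed = 1)
    p <- generate_parcels(cfg)
    list(cfg = cfg, parcels = p, roads = generate_roads(cfg),
         buildings = generate_buildings(cfg, p))
  })
}

default_pipeline_dir <- function() {
  cached("default_pipeline_dir", {
    d <- file.path(tempdir(), "pipe_default")
    unlink(d, recursive = TRUE)
    cfgp <- pipeline_config(city = city_config(seed = 11),
                            raster = list(res = 200),
                            gwr = list(nperm = 199))
    suppressWarnings(suppressMessages(run_pipeline(cfgp, d)))
    d
  })
}

default_panel <- function() {
  cached("default_panel", {
    dc <- default_city_static()
    generate_monitoring_panel(dc$cfg, dc$parcels, dc$roads)
  })
}

# construct a vector with an exact in-sample correlation with `anchor`
make_cor_vec <- function(anchor, rho) {
  zs <- function(x) (x - mean(x)) / stats::sd(x)
  e <- stats::residuals(stats::lm(stats::rnorm(length(anchor)) ~ anchor))
  rho * zs(anchor) + sqrt(1 - rho^2) * zs(e)
}
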