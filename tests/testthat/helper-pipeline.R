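# Drives the full CLI pipeline on the packaged demo scene; used by both
# the CLI tests and the determinism check.
run_demo_pipeline <- function(out) {
  demo_cfg <- system.file("extdata", "demo_scene.yaml", package = "neurokym")
  stopifnot(nzchar(demo_cfg))
  st1 <- neurokym_cli(c("simulate", "scene", "--config", demo_cfg,
                        "--out", out, "--log-level", "quiet"))
  cfg2 <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    segment = list(stack = file.path(out, "stack.tif"), channel = "actin",
                   threshold = 50, seed_voxel = c(40, 19, 4)),
    kymograph = list(stack = file.path(out, "stack.tif"),
                     masks = file.path(out, "masks.tif"),
                     channel = "actin", statistic = "sum",
                     tracks = file.path(out, "tracks.csv"),
                     track_id = "organelle"),
    compartments = list(stack = file.path(out, "stack.tif"),
                        masks = file.path(out, "masks.tif"),
                        channel = "adhesion"),
    velocity = list(tracks = file.path(out, "tracks.csv"),
                    frame_interval_s = 120, min_consecutive = 5)
  ), cfg2)
  st2 <- neurokym_cli(c("segment", "--config", cfg2, "--out", out,
                        "--log-level", "quiet"))
  st3 <- neurokym_cli(c("kymograph", "--config", cfg2, "--out", out,
                        "--log-level", "quiet"))
  st4 <- neurokym_cli(c("compartments", "--config", cfg2, "--out", out,
                        "--log-level", "quiet"))
  st5 <- neurokym_cli(c("velocity", "--config", cfg2, "--out", out,
                        "--log-level", "quiet"))
  unlink(cfg2)
  c(st1, st2, st3, st4, st5)
}

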