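#!/usr/bin/env Rscript
# Calibration of the detector's one free structural configuration.
#
# Three published parameter counts triple-constrain the configuration
# (width multiplier, final-stage bottleneck count, involution K/G/r, and
# the backbone repeat plan):
#   * final backbone stage, convolution core:  4.1 M
#   * final backbone stage, involution core:   1.8 M
#   * full backbone with involution core:     10.1 M
# (and, as a consistency check, the convolution-twin backbone: 12.4 M).
#
# This script searches the candidate grid and prints every configuration
# that satisfies all targets simultaneously after rounding to one
# decimal in millions. The package defaults (width 0.75, repeats
# (1, 3, 7, 2) i.e. base (3, 9, 21, 6) at depth 1/3, K = 7, r = 4,
# G = C/16) are the unique minimal-complexity solution found here.

suppressMessages(library(ardnet))

targets <- c(stage_conv = 4.1, stage_inv = 1.8, backbone_inv = 10.1,
             backbone_conv = 12.4)

hit <- function(x, t) round(x / 1e6, 1) == t

found <- list()
for (width in c(0.5, 0.625, 0.75, 1.0)) {
  for (n_final in 1:3) {
    for (K in c(3, 5, 7)) {
      for (r in c(2, 4)) {
        cfg <- ardnet_config(width_multiple = width,
                             base_depths = c(3, 9, 21, n_final * 3),
                             depth_multiple = 1 / 3,
                             inv_K = K, inv_r = r)
        sc <- count_parameters(build_final_stage(cfg, "conv"))
        si <- count_parameters(build_final_stage(cfg, "involution"))
        if (!hit(sc, targets["stage_conv"]) ||
            !hit(si, targets["stage_inv"])) next
        # stage constraints met; now search the repeat plan for the
        # backbone total
        for (n2 in 1:3) for (n4 in 1:7) for (n6 in 1:8) {
          cfg2 <- ardnet_config(width_multiple = width,
                                base_depths = 3 * c(n2, n4, n6, n_final),
                                depth_multiple = 1 / 3,
                                inv_K = K, inv_r = r)
          bi <- count_parameters(build_backbone(cfg2))
          if (!hit(bi, targets["backbone_inv"])) next
          cfg3 <- cfg2; cfg3$backbone_involution <- FALSE
          bc <- count_parameters(build_backbone(cfg3))
          ok_twin <- hit(bc, targets["backbone_conv"])
          cat(sprintf(
            "width=%.3f repeats=(%d,%d,%d,%d) K=%d r=%d: stage conv %.3fM, stage inv %.3fM, backbone inv %.3fM, conv twin %.3fM%s\n",
            width, n2, n4, n6, n_final, K, r, sc / 1e6, si / 1e6,
            bi / 1e6, bc / 1e6, if (ok_twin) "  [all targets met]" else ""))
        }
      }
    }
  }
}
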