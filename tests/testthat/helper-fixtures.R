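# Small fixtures built in code.

# a stack with a uniform green block and hand-placed red voxels
block_stack <- function(d = c(12, 12, 12), green_level = 255) {
  g <- array(green_level, d)
  r <- array(0L, d)
  voxel_stack(g, r)
}

set_red <- function(stack, vox, level = 255L) {
  stack$red[vox] <- level
  stack
}

# map detected enclosure flags back onto planted record ids
recovered_flags <- function(sim, q) {
  m <- match_planted(q$components, sim$truth)
  det <- rep(FALSE, nrow(sim$truth$mito_records))
  det[m[q$enclosures$enclosed]] <- TRUE
  list(match = m, detected = det,
       planted = sim$truth$mito_records$planted_enclosed)
}
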