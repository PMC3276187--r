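# Shared fixtures: small noise-free synthetic pot frames with known geometry.

# logical H x W disk mask centred at (cx, cy) (0-based), radius r
disk_mask <- function(H, W, cx, cy, r) {
  xs <- (0:(W - 1)); ys <- (0:(H - 1))
  outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r^2)
}

# noise-free pot frame: soil background with a disk-shaped plant, under
# global light level L (colours mirror the synthetic-scene defaults)
pot_frame <- function(mask, L = 1,
                      soil = c(0.30, 0.38, 0.26),
                      plant = c(0.12, 0.55, 0.10)) {
  H <- nrow(mask); W <- ncol(mask)
  px <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    m <- matrix(soil[ch], H, W)
    m[mask] <- plant[ch]
    px[, , ch] <- m * L
  }
  px
}

# frame record as consumed by process_day()/run_stack()
frame_record <- function(pixels, timestamp, day_index, within_day) {
  list(timestamp = timestamp, pixels = pixels,
       day_index = day_index, within_day = within_day)
}

make_stack <- function(frames, pot_id = "pot01", accession = "accA",
                       season = "spring") {
  structure(list(pot_id = pot_id, flat_id = "flatT", accession = accession,
                 season = season, frames = frames),
            class = "plant_stack")
}
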