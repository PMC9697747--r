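# Independent CIEDE2000 oracle: a literal, step-numbered transcription of
# the published worked procedure (Sharma, Wu & Dalal 2005), written before
# and apart from the package implementation. Degrees throughout, converted
# at each trig call; no package internals are used.
ciede2000_oracle <- function(lab1, lab2, kL = 1, kC = 1, kH = 1) {
  deg2rad <- function(d) d * pi / 180
  rad2deg <- function(r) r * 180 / pi
  L1 <- lab1[1]; a1 <- lab1[2]; b1 <- lab1[3]
  L2 <- lab2[1]; a2 <- lab2[2]; b2 <- lab2[3]

  # Step 1: C'i, h'i
  C1ab <- sqrt(a1 * a1 + b1 * b1)
  C2ab <- sqrt(a2 * a2 + b2 * b2)
  Cab_bar <- (C1ab + C2ab) / 2
  G <- 0.5 * (1 - sqrt(Cab_bar^7 / (Cab_bar^7 + 25^7)))
  a1p <- (1 + G) * a1
  a2p <- (1 + G) * a2
  C1p <- sqrt(a1p * a1p + b1 * b1)
  C2p <- sqrt(a2p * a2p + b2 * b2)
  h1p <- if (b1 == 0 && a1p == 0) 0 else (rad2deg(atan2(b1, a1p)) %% 360)
  h2p <- if (b2 == 0 && a2p == 0) 0 else (rad2deg(atan2(b2, a2p)) %% 360)

  # Step 2: dL', dC', dH'
  dLp <- L2 - L1
  dCp <- C2p - C1p
  if (C1p * C2p == 0) {
    dhp <- 0
  } else if (abs(h2p - h1p) <= 180) {
    dhp <- h2p - h1p
  } else if (h2p - h1p > 180) {
    dhp <- h2p - h1p - 360
  } else {
    dhp <- h2p - h1p + 360
  }
  dHp <- 2 * sqrt(C1p * C2p) * sin(deg2rad(dhp / 2))

  # Step 3: means, weighting functions, rotation, combination
  Lp_bar <- (L1 + L2) / 2
  Cp_bar <- (C1p + C2p) / 2
  if (C1p * C2p == 0) {
    hp_bar <- h1p + h2p
  } else if (abs(h1p - h2p) <= 180) {
    hp_bar <- (h1p + h2p) / 2
  } else if (h1p + h2p < 360) {
    hp_bar <- (h1p + h2p + 360) / 2
  } else {
    hp_bar <- (h1p + h2p - 360) / 2
  }
  T_ <- 1 - 0.17 * cos(deg2rad(hp_bar - 30)) +
    0.24 * cos(deg2rad(2 * hp_bar)) +
    0.32 * cos(deg2rad(3 * hp_bar + 6)) -
    0.20 * cos(deg2rad(4 * hp_bar - 63))
  dtheta <- 30 * exp(-(((hp_bar - 275) / 25)^2))
  RC <- 2 * sqrt(Cp_bar^7 / (Cp_bar^7 + 25^7))
  SL <- 1 + (0.015 * (Lp_bar - 50)^2) / sqrt(20 + (Lp_bar - 50)^2)
  SC <- 1 + 0.045 * Cp_bar
  SH <- 1 + 0.015 * Cp_bar * T_
  RT <- -sin(deg2rad(2 * dtheta)) * RC

  sqrt((dLp / (kL * SL))^2 + (dCp / (kC * SC))^2 + (dHp / (kH * SH))^2 +
         RT * (dCp / (kC * SC)) * (dHp / (kH * SH)))
}
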