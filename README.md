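# suctionpower

Suction-feeding fishes expand the mouth cavity explosively: axial muscles
elevate the neurocranium and retract the pectoral girdle, volume rises,
intra-oral pressure drops below ambient, and water (and prey) rushes in.
Quantifying where that power comes from requires stitching together several
measurements made on the same strike: marker-based X-ray motion capture of
the bones (XROMM), muscle length change from implanted intramuscular
markers (fluoromicrometry), a dynamic endocast of the mouth cavity, and an
intra-oral pressure recording.

**suctionpower** is the analysis pipeline between those raw measurements
and the numbers a comparative biomechanist reports. From per-frame 3D
marker coordinates and a pressure trace it computes:

* per-bone rigid-body transforms by orthogonal least squares (Kabsch SVD
  with reflection guard), with tracking precision estimated from intra-bone
  marker-pair distances;
* joint kinematics in duplicated anatomical coordinate systems with an
  intrinsic **z-y-x** Euler decomposition (`+rz` = dorsal rotation /
  elevation; `-rz` = depression / retraction), timed relative to peak gape;
* muscle strain and strain rate, `strain = 100 (L_i - L) / L_i` (positive
  = shortening) and `rate = -(dL/dt)/L_i` in initial lengths per second,
  for intramuscular marker chains (per subregion and whole region) and for
  three-fiber cranial muscles on animated bones;
* dynamic mouth volume as the per-frame 3D **alpha-shape** volume of the
  endocast landmark cloud (alpha = circumsphere-radius threshold, default
  2; unilateral volume doubled assuming bilateral symmetry), with the 3D
  Delaunay tetrahedralization implemented in compiled code;
* instantaneous mouth-expansion power `P(t) = -p(t) * dV/dt` (Pa times
  m^3/s = W), its maximum, the peak-power window (frames within 25% of
  maximum), and peak power normalized by muscle mass, body mass and
  maximum volume change.

Kinematic signals are zero-phase Butterworth filtered (40 Hz for motion,
300 Hz for pressure at its native rate). A seeded synthetic-strike
generator (`simulate_strike()`) produces complete strikes with analytically
known ground truth — prescribed joint angle pulses, subregion strains, an
endocast with closed-form volume, and a pressure trace inverted from a
target peak power — so every stage has an exact recovery test without any
external recordings.

## Worked example

Simulate a strike at the study's scales (5 deg cranial elevation, 8 deg
girdle retraction, 4–8% hypaxial strain, 0.08 mm marker noise, 5 W target
peak power) and run the full pipeline:

```r
library(suctionpower)

b <- simulate_strike(synthetic_truth(), seed = 42)
r <- analyze_strike(b)
print(r)
#> <strike_result> 241 frames @ 300 Hz; peak gape at t = 0.450 s
#>   peak power 4.806 W at t = 0.373 s; peak pressure -17283 Pa; max volume 52.8 cm^3
#>   neurocranium: peak rz 3.69 deg during peak power
#>   cleithrum: peak rz -4.08 deg during peak power

max(r$kinematics$neurocranium$rz_deg)   # recovered elevation amplitude
#> [1] 4.949  (truth: 5 deg)
r$power$max_power_w                     # recovered peak expansion power
#> [1] 4.806  (truth: 5 W)
```

Reading the output: peak gape defines t = 0 for the strike; peak expansion
power lands ~0.08 s *before* peak gape, while the mouth is still opening
and dV/dt is largest. The "peak rz during peak power" lines give each
joint's largest z-rotation inside the peak-power window — the cleithrum is
already retracting (negative rz) during peak power, while elevation is
still building toward its later maximum, which is why the windowed value
(3.69 deg) is below the 5 deg amplitude. The recovered peak power sits ~4%
low because the endocast volume of a finitely sampled landmark cloud is an
inscribed estimate; the noiseless pipeline recovers the same target within
1.5%.

Per-strike CSV exports and per-individual mean ± s.e.m. tables:

```r
write_strike_result(r, "out/Cat1_01")
summarize_individuals(strikes_df, individual_ids)
```

A thin command-line wrapper covers the same three steps
(`inst/cli/suctionpower.R simulate | analyze | report`).

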