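library(borealmc)
scene <- lake_scene_profile("figure-depths", water = "LAN", C = 10)
scene
res <- run_transport(scene, source_spec(700),
                     transport_config(n_photons = 2e5, seed = 1))
res
cm <- measure_debris_contrast(reflectance_image(res), attr(scene, "cylinders"))
print(cm[, c("debris_depth_m", "I_W", "I_b", "contrast", "spread")], digits = 3)
sw <- run_sweep(sweep_spec(wavelengths = seq(400, 800, 100), water = "LAN",
                           C_values = 10, n_photons = 1e5, base_seed = 1))
print(max_visible_depth(sw, cutoff = 0.10))
recommend_wavelengths(sw)
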