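seed: 1
ground_extent: 40.0
ground_texture:
  noise_scale: 1.0
  albedo_lo: 0.5
  albedo_hi: 0.5
trees:
- position:
  - 0.0
  - 10.0
  trunk_radius: 0.25
  trunk_height: 3.0
  canopy_radius: 2.0
  albedo: 0.2
- position:
  - 10.0
  - 0.0
  trunk_radius: 0.25
  trunk_height: 3.0
  canopy_radius: 2.0
  albedo: 0.2
- position:
  - 0.0
  - -10.0
  trunk_radius: 0.25
  trunk_height: 3.0
  canopy_radius: 2.0
  albedo: 0.2
- position:
  - -10.0
  - 0.0
  trunk_radius: 0.25
  trunk_height: 3.0
  canopy_radius: 2.0
  albedo: 0.2
clutter: []
sun:
  azimuth_deg: 0.0
  elevation_deg: 60.0
  shadow_darkening: 1.0
sky_color:
- 135.0
- 206.0
- 250.0
background:
  type: none
  color:
  - 160.0
  - 200.0
  - 235.0
  sphere_radius_m: 500.0
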