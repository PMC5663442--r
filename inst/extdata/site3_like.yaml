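seed: 1
ground_extent: 80.0
ground_texture:
  noise_scale: 1.2
  albedo_lo: 0.35
  albedo_hi: 0.65
trees:
- position:
  - 12.206768835468077
  - 21.768359882446461
  trunk_radius: 0.345550903239928
  trunk_height: 5.072802762815627
  canopy_radius: 4.549706024565239
  albedo: 0.180500428168743
- position:
  - 18.086504543229903
  - -0.430047492949175
  trunk_radius: 0.400651595284944
  trunk_height: 5.994675236652256
  canopy_radius: 4.582139300022391
  albedo: 0.194704015140887
- position:
  - -15.710184330082189
  - -17.038989876003559
  trunk_radius: 0.379058465582784
  trunk_height: 5.163482159583509
  canopy_radius: 4.416164769362695
  albedo: 0.226308208172559
- position:
  - -26.562885153821785
  - 9.255373396532246
  trunk_radius: 0.397146798198992
  trunk_height: 6.301136842692358
  canopy_radius: 5.705684175045462
  albedo: 0.219088205623557
clutter: []
sun:
  azimuth_deg: 315.0
  elevation_deg: 50.0
  shadow_darkening: 0.55
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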