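seed: 1
ground_extent: 30.0
ground_texture:
  noise_scale: 0.4
  albedo_lo: 0.2
  albedo_hi: 0.8
trees:
- position:
  - 3.579816749001037
  - 6.383895718500016
  trunk_radius: 0.142775451619964
  trunk_height: 2.548535175210418
  canopy_radius: 1.529823614739144
  albedo: 0.150500428168743
- position:
  - 4.819926708180102
  - 1.440356715554854
  trunk_radius: 0.170325797642472
  trunk_height: 3.163116824434837
  canopy_radius: 1.549283580013434
  albedo: 0.164704015140887
- position:
  - -0.781916605129149
  - -6.679797228954373
  trunk_radius: 0.159529232791392
  trunk_height: 2.608988106389006
  canopy_radius: 1.449698861617617
  albedo: 0.196308208172559
- position:
  - -6.8790933780871
  - -4.779314251453565
  trunk_radius: 0.168573399099496
  trunk_height: 3.367424561794905
  canopy_radius: 2.223410505027277
  albedo: 0.189088205623557
- position:
  - -7.21494524729797
  - -2.055335614481975
  trunk_radius: 0.164681690875586
  trunk_height: 2.954791364070843
  canopy_radius: 1.288520884534955
  albedo: 0.173458986504193
clutter:
- position:
  - -1.844069993828883
  - 1.225776171221436
  radius: 0.105768903592252
  albedo: 0.132819201187522
- position:
  - 1.018703624467144
  - 0.826632808113761
  radius: 0.116656551194319
  albedo: 0.287820733976423
- position:
  - 2.351925846201248
  - 0.068054615463381
  radius: 0.168221083872777
  albedo: 0.275283515920455
- position:
  - 1.880899605492088
  - 0.524086031327298
  radius: 0.105780720406619
  albedo: 0.225600028306735
- position:
  - 1.689717813545423
  - -0.136924775183321
  radius: 0.213289949302998
  albedo: 0.375830061567831
- position:
  - 0.952239991316614
  - -1.896467876652064
  radius: 0.188690109054733
  albedo: 0.554598687559155
- position:
  - 0.431806472372484
  - -1.492193551003352
  radius: 0.240307622915861
  albedo: 0.29709479807716
- position:
  - -2.797948106072893
  - -0.431269056022346
  radius: 0.271682114398573
  albedo: 0.427604175558008
- position:
  - -0.488883265122195
  - 0.73327284303126
  radius: 0.1610220192415
  albedo: 0.219324297453204
- position:
  - 0.219970128528378
  - 0.872084970412105
  radius: 0.109089438522642
  albedo: 0.389991466575884
sun:
  azimuth_deg: 315.0
  elevation_deg: 40.0
  shadow_darkening: 0.4
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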