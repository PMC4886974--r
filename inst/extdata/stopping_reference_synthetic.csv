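# Synthetic reference stopping-power table (computed, not measured).
# Full Bethe formula, 0.307075*(Z/A) MeV cm^2/g prefactor, no shell or
# density corrections; see tools/make_reference_fixture.py.
material,E_MeV,S_MeV_per_cm
water,10,45.9517
water,15,33.0486
water,20,26.1376
water,30,18.7898
water,40,14.8926
water,50,12.4584
water,70,9.56351
water,100,7.29097
water,130,6.02161
water,160,5.20919
water,200,4.49241
water,250,3.91096
a150,10,52.5035
a150,15,37.7001
a150,20,29.7862
a150,30,21.3856
a150,40,16.9362
a150,50,14.1598
a150,70,10.8609
a150,100,8.2738
a150,130,6.82985
a150,160,5.90615
a150,200,5.09152
a150,250,4.43091
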