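{"vid":"38183","rsids":["81002812"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["A"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2016-04-15","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2016-09-16","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-08-18","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2014-09-03","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2015-10-02","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2016-03-01","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"42965","rsids":["397516187"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["C"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2016-12-15","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2014-05-13","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2016-07-22","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2013-09-25","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2017-07-24","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"89172","rsids":["587779204"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["G"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2013-09-05","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2017-08-30","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2017-07-07","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"US","last_evaluated":"2017-05-15","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"US","last_evaluated":"2017-05-10","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2016-05-17","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"90099","rsids":["267607893"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["T"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2013-09-05","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2015-07-02","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2016-07-05","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"91028","rsids":["63751469"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["A"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2015-10-28","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-06-09","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2017-09-07","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"91030","rsids":["63750084"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["C"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2015-10-28","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2014-05-27","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2014-10-20","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-07-14","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"91033","rsids":["63750808"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["G"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2015-10-28","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-08-17","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2016-01-18","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"91035","rsids":["63751007"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["T"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2015-10-28","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2014-06-20","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-12-20","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"91328","rsids":["267608161"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["A"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2013-09-05","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2017-07-12","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-04-26","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2017-12-05","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2016-03-25","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
{"vid":"91330","rsids":["587779335"],"cvcs":"US","stars":3,"variant_type":"Simple","alt_alleles":["C"],"conditions":[],"cv_last_evaluated":null,"assertions":[{"significance":"US","last_evaluated":"2015-11-24","submitter_category":"expert_panel","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-11-21","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-07-09","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LP","last_evaluated":"2014-10-30","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"LB","last_evaluated":"2016-07-14","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]},{"significance":"P","last_evaluated":"2017-03-27","submitter_category":"criteria_provided","submitter_name":null,"conditions":[]}]}
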