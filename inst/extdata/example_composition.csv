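food_code,name,group,protein_g_per_100g,energy_kcal_per_100g
BR01,white bread,bread,7.9,265
BR02,wholemeal bread,bread,9.3,250
BR03,currant bread,bread,6.8,290
BR04,rye bread,bread,8.4,220
BR05,protein-rich multigrain bread,bread,13.5,255
YO01,full-fat yoghurt,"yoghurt, cream desserts and pudding",3.9,80
YO02,vanilla custard,"yoghurt, cream desserts and pudding",2.9,95
YO03,cream pudding,"yoghurt, cream desserts and pudding",2.6,120
YO04,skyr,"yoghurt, cream desserts and pudding",10.5,65
SO01,vegetable soup,soups,1.2,35
SO02,tomato soup,soups,1.5,45
SO03,pea soup with smoked sausage,soups,4.8,90
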