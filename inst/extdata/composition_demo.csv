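food_id,name,group,subgroup,is_wholegrain,is_low_fat,serve_size_g,energy_kj,protein_g,fat_g,sat_fat_g,mono_g,poly_g,carb_g,sugars_g,starch_g,fiber_g,sodium_mg,alcohol_g,density_g_ml
spinach,"Spinach, cooked",vegetables,green_veg,FALSE,FALSE,75,87.5,2.9,0.4,0.1,0.1,0.2,1.4,0.4,1,2.2,79,0,NA
carrot,"Carrot, raw",vegetables,orange_veg,FALSE,FALSE,75,156.3,0.9,0.2,0.05,0.05,0.1,8,4.5,3.5,2.8,69,0,NA
lentils,"Lentils, boiled",vegetables,legumes,FALSE,FALSE,75,501.8,9,0.4,0.05,0.1,0.25,20,1.8,18.2,7.9,2,0,NA
potato,"Potato, boiled",vegetables,starchy_veg,FALSE,FALSE,75,321.6,2,0.1,0.03,0.01,0.04,17,0.8,16.2,2.2,6,0,NA
capsicum,"Capsicum, raw",vegetables,other_veg,FALSE,FALSE,75,128.3,1,0.3,0.06,0.03,0.15,6,4.2,1.8,2.1,3,0,NA
apple,"Apple, raw",fruit,pome_fruit,FALSE,FALSE,150,202.9,0.3,0.2,0.03,0.01,0.06,11.4,10.4,1,2.4,1,0,NA
orange,"Orange, raw",fruit,citrus_fruit,FALSE,FALSE,150,157.6,0.9,0.1,0.02,0.02,0.03,8.3,8.3,0,2.2,0,0,NA
strawberry,"Strawberries, raw",fruit,berry_fruit,FALSE,FALSE,150,118.2,0.7,0.3,0.02,0.04,0.16,5.7,4.9,0.8,2,1,0,NA
banana,"Banana, raw",fruit,tropical_fruit,FALSE,FALSE,150,363.8,1.1,0.3,0.1,0.03,0.07,20,12,8,2.6,1,0,NA
peach,"Peach, raw",fruit,stone_fruit,FALSE,FALSE,150,183.2,0.9,0.25,0.02,0.09,0.09,9.5,8.4,1.1,1.5,0,0,NA
wholegrain_bread,Wholegrain bread,grains,bread,TRUE,FALSE,40,903.1,9.7,2.8,0.6,0.8,1.2,38,2.8,35.2,6.8,400,0,NA
rolled_oats,"Rolled oats, raw",grains,cereal,TRUE,FALSE,30,1485.6,13,8,1.4,2.6,3,58,1,57,10,2,0,NA
white_bread,White bread,grains,bread,FALSE,FALSE,40,988.5,8.5,2.5,0.5,0.6,1,45,3,42,2.7,450,0,NA
white_rice,"White rice, boiled",grains,cereal,FALSE,FALSE,100,524.6,2.7,0.3,0.08,0.09,0.1,28,0.1,27.9,0.4,1,0,NA
chicken_breast,"Chicken breast, grilled",meat_alt,poultry,FALSE,FALSE,80,660.2,31,3.6,1,1.4,0.8,0,0,0,0,74,0,NA
eggs,"Eggs, boiled",meat_alt,egg,FALSE,FALSE,120,577.4,12.6,9.5,3.1,3.7,1.9,0.7,0.7,0,0,140,0,NA
tofu,"Tofu, firm",meat_alt,soy,FALSE,FALSE,170,459.4,12,6,0.9,1.5,3.4,2,0.7,1.3,0.9,7,0,NA
almonds,"Almonds, raw",meat_alt,nuts_seeds,FALSE,FALSE,30,2357.3,21,50,3.8,32,12,9,4.4,4.6,12.5,1,0,NA
skim_milk,Skim milk,dairy_alt,milk,FALSE,TRUE,250,146.7,3.5,0.1,0.07,0.02,0.01,5,5,0,0,44,0,1.03
lowfat_yoghurt,Low-fat yoghurt,dairy_alt,yoghurt,FALSE,TRUE,200,217.8,5.5,0.2,0.1,0.05,0.02,7,7,0,0,60,0,NA
soy_milk,"Soy milk, fortified",dairy_alt,milk_substitute,FALSE,TRUE,250,164.4,3.3,1.8,0.3,0.4,1,2.5,2,0.5,0.5,40,0,1.03
full_cream_milk,Full cream milk,dairy_alt,milk,FALSE,FALSE,250,276.9,3.3,3.8,2.4,1,0.2,4.8,4.8,0,0,40,0,1.03
cheddar,Cheddar cheese,dairy_alt,cheese,FALSE,FALSE,40,1647.7,25,33,21,9,1.3,0.1,0.1,0,0,650,0,NA
fried_snack,Fried savoury snack,discretionary,savoury_snack,FALSE,FALSE,50,2030,5,30,15,10,4,50,45,5,1,1500,0,NA
chocolate,Milk chocolate,discretionary,confectionery,FALSE,FALSE,25,2189.4,7.5,30,18,9,1.5,57,51,6,2,80,0,NA
bottled_water,Bottled water,beverage_water,water,FALSE,FALSE,250,0,0,0,0,0,0,0,0,0,0,0,0,1
cola,Cola soft drink,beverage_ssb,soft_drink,FALSE,FALSE,250,177,0,0,0,0,0,10.6,10.6,0,0,4,0,1.04
orange_juice,Orange juice,beverage_other,juice,FALSE,FALSE,250,162.5,0.6,0.1,0.01,0.02,0.02,8.9,8.1,0.8,0.3,2,0,1.04
beer,"Beer, full strength",alcohol_bev,beer,FALSE,FALSE,375,152.5,0.4,0,0,0,0,2.3,0.2,2.1,0,4,3.7,1.008
spirits,Spirits (40% v/v),alcohol_bev,spirits,FALSE,FALSE,30,1102,0,0,0,0,0,0,0,0,0,1,38,0.95
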